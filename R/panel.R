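#' The 23-compound triazolopeptide panel
#'
#' Loads the shipped fixture table transcribing the published panel: compound
#' ids, subseries, sequences, the printed general formulas and calculated and
#' measured m/z values (with the reported charge state), retention times
#' (measured metadata, never computed), percent inhibition at 10 uM with SD,
#' and, where reported, logIC50 with SE and the dose-response R-squared.
#'
#' Note one transcription-faithful quirk: the printed calculated m/z of
#' compound 23 (507.3020) is arithmetically inconsistent with its own printed
#' formula C19H34N14O3, whose monoisotopic [M+H]+ is 507.3011 — the row's
#' measured value. See [validate_panel()] and the methods vignette.
#'
#' @return Data frame with one row per compound.
#' @export
triazolopeptide_panel <- function() {
  path <- system.file("extdata", "triazolopeptide_panel.csv",
                      package = "trzsar", mustWork = TRUE)
  read_compound_table(path)
}

#' Reproduce the panel structure-activity models
#'
#' Builds the descriptor matrix over the 23-compound panel and fits both
#' published correlation models: Model 1 (inhibition on the raw
#' guanidine-to-guanidine distance) and Model 2 (inhibition on the
#' min-max-normalised distance plus the `am_2N` and `Trl2_CN` indicators).
#'
#' @param panel Compound table (default: the shipped panel). Must carry
#'   `id`, `sequence` and `inh` columns.
#' @param convention Ring-traversal convention for the distance descriptor
#'   (see [topological_distance()]).
#' @return List with `descriptors`, `model1`, `model2` (both `sar_ols`) and
#'   the `panel` used.
#' @export
panel_models <- function(panel = triazolopeptide_panel(),
                         convention = "backbone") {
  stopifnot(all(c("id", "sequence", "inh") %in% names(panel)))
  desc <- build_descriptor_matrix(panel[, c("id", "sequence")],
                                  convention = convention)
  stopifnot(identical(desc$id, as.character(panel$id)))
  m1 <- ols_fit(desc[, "dis_N_C", drop = FALSE], panel$inh)
  m2 <- ols_fit(desc[, c("dis_N_C_norm", "am_2N", "Trl2_CN")], panel$inh)
  list(descriptors = desc, model1 = m1, model2 = m2, panel = panel)
}
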