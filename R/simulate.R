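# run expr under a local RNG state seeded with `seed` (NULL = use current RNG)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.default_arms <- c("Lys(Har)", "D-Lys(Har)", "D-Lys(D-Har)", "Lys(Fmoc-Har)",
                   "Dab(Har)", "Dap(Har)", "Har", "Har-Lys", "Har-6Ahx",
                   "Har-5Ava", "Har-Ala", "Har-Gly")
.default_linker_aa <- c("Gly", "Ala", "Pro", "Phe")

#' Generate a synthetic compound panel
#'
#' Draws sequences from the notation grammar the published panel spans: a
#' guanidine-bearing "arm" (branched or backbone-attached homoarginine), a
#' linker of 1-3 units in which each unit is a glycyl-triazole with
#' probability `p_triazole` (otherwise a standard amino acid), and the
#' C-terminal arginine anchor. Every generated sequence parses, assembles,
#' and carries exactly two guanidine groups.
#'
#' @param n Number of compounds.
#' @param seed Integer seed (generation is deterministic given the seed).
#' @param p_triazole Probability that a linker unit is a triazole unit.
#' @param linker_len Candidate linker lengths (units), sampled uniformly.
#' @param arms Candidate arm prefixes.
#' @return Data frame with columns `id` and `sequence` (canonical strings).
#' @export
gen_compound_panel <- function(n = 23, seed = NULL, p_triazole = 0.7,
                               linker_len = 1:3, arms = .default_arms) {
  with_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      arm <- sample(arms, 1)
      len <- if (length(linker_len) == 1) linker_len else sample(linker_len, 1)
      linker <- character(len)
      for (j in seq_len(len)) {
        linker[j] <- if (stats::runif(1) < p_triazole) {
          "GlyΨ[Trl]"
        } else {
          # no proline directly after a triazole unit: the ring nitrogen
          # derives from a primary amine (diazotransfer), which a secondary
          # proline amine cannot provide
          after_trz <- j > 1 && linker[j - 1] == "GlyΨ[Trl]"
          pool <- if (after_trz) setdiff(.default_linker_aa, "Pro")
                  else .default_linker_aa
          sample(pool, 1)
        }
      }
      text <- paste(c(arm, linker, "Arg"), collapse = "-")
      seqs[i] <- canonical_string(parse_sequence(text))
    }
    data.frame(id = sprintf("s%02d", seq_len(n)), sequence = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Generate activities from the linear structure-activity model
#'
#' `inh = b0 + b1 * dis_N_C_norm + b2 * am_2N + b3 * Trl2_CN + N(0, sigma)`,
#' clipped to [0, 100] (clip events are counted in the `clipped` column and
#' reported with a message). The default coefficients are the three-variable
#' model's published values; the default residual `sigma` is calibrated as
#' the residual standard deviation of that model refitted on the shipped
#' 23-compound panel, so that panels of the same size reproduce its
#' R-squared on average.
#'
#' @param descriptors Descriptor matrix from [build_descriptor_matrix()].
#' @param coefficients Numeric length 4: intercept, normalised-distance,
#'   `am_2N` and `Trl2_CN` coefficients.
#' @param sigma Residual standard deviation (percent points); `NULL` =
#'   calibrated default.
#' @param seed Integer seed.
#' @return Data frame `id`, `inh`, `clipped`.
#' @export
gen_activity_from_model <- function(descriptors,
                                    coefficients = c(8.6, 20.9, 8.7, 8.6),
                                    sigma = NULL, seed = NULL) {
  stopifnot(all(c("id", "dis_N_C_norm", "am_2N", "Trl2_CN") %in%
                  names(descriptors)),
            length(coefficients) == 4)
  if (is.null(sigma)) sigma <- calibrated_activity_sigma()
  with_seed(seed, {
    mu <- coefficients[1] +
      coefficients[2] * descriptors$dis_N_C_norm +
      coefficients[3] * descriptors$am_2N +
      coefficients[4] * descriptors$Trl2_CN
    inh <- mu + stats::rnorm(length(mu), 0, sigma)
    clipped <- inh < 0 | inh > 100
    if (any(clipped)) {
      message(sum(clipped), " activity value(s) clipped to [0, 100]")
    }
    data.frame(id = descriptors$id, inh = pmin(pmax(inh, 0), 100),
               clipped = clipped, stringsAsFactors = FALSE)
  })
}

#' @rdname gen_activity_from_model
#' @export
calibrated_activity_sigma <- function() {
  models <- panel_models()
  models$model2$sigma
}

#' Generate synthetic competitive-ELISA plate signals
#'
#' Inverts the percent-inhibition formula: per replicate,
#' `S = NS + (Pmax - NS) * (1 - inh_true / 100) + N(0, sigma)`.
#'
#' @param inh_true True percent inhibition (vectorised over compounds).
#' @param NS,Pmax Negative-control and maximum binding signals
#'   (`Pmax > NS`).
#' @param sigma Additive Gaussian signal noise.
#' @param replicates Replicates per compound (two independent experiments in
#'   triplicate gives the default 6).
#' @param seed Integer seed.
#' @return Data frame `compound`, `replicate`, `S`, `NS`, `Pmax`.
#' @export
gen_elisa_plate <- function(inh_true, NS = 0.1, Pmax = 1.0, sigma = 0.02,
                            replicates = 6, seed = NULL) {
  if (Pmax <= NS) stop("Pmax must exceed NS", call. = FALSE)
  ids <- names(inh_true)
  if (is.null(ids)) ids <- as.character(seq_along(inh_true))
  with_seed(seed, {
    out <- expand.grid(replicate = seq_len(replicates), compound = ids,
                       stringsAsFactors = FALSE)[, 2:1]
    mu <- NS + (Pmax - NS) * (1 - inh_true[out$compound] / 100)
    out$S <- mu + stats::rnorm(nrow(out), 0, sigma)
    out$NS <- NS
    out$Pmax <- Pmax
    out
  })
}

#' Generate a synthetic dose-response curve
#'
#' Log-logistic expectation plus additive Gaussian noise; the defaults
#' emulate the best compound's published curve (logIC50 = -5.076).
#'
#' @param logIC50 Molar log10 IC50.
#' @param hill Hill slope.
#' @param conc Molar concentration grid.
#' @param sigma Noise standard deviation in percent points.
#' @param seed Integer seed.
#' @return Data frame `conc`, `inh`.
#' @export
gen_dose_response <- function(logIC50 = -5.076, hill = 1,
                              conc = 10^seq(-7, -3, length.out = 8),
                              sigma = 0, seed = NULL) {
  with_seed(seed, {
    mu <- 100 / (1 + 10^(hill * (logIC50 - log10(conc))))
    data.frame(conc = conc, inh = mu + stats::rnorm(length(conc), 0, sigma))
  })
}

#' Generate a synthetic stability-decay series
#'
#' Exponential decay from 100 percent plus Gaussian noise; the default time
#' grid follows the published sampling scheme (0-48 h every 8 h).
#' `t_half = Inf` yields a flat series.
#'
#' @param t_half Half-life in hours (`Inf` for no degradation).
#' @param times Sampling times in hours.
#' @param sigma Noise standard deviation in percent points.
#' @param seed Integer seed.
#' @return Data frame `time`, `fraction`.
#' @export
gen_decay_series <- function(t_half = 48, times = seq(0, 48, by = 8),
                             sigma = 0, seed = NULL) {
  stopifnot(t_half > 0)
  with_seed(seed, {
    k <- if (is.finite(t_half)) log(2) / t_half else 0
    mu <- 100 * exp(-k * times)
    data.frame(time = times,
               fraction = mu + stats::rnorm(length(times), 0, sigma))
  })
}
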