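# Synthetic-data generators mirroring the statistical structure of the
# transport assays and the compound library, so every pipeline stage is
# testable with known ground truth. The generators emulate the assumed
# models only (asymptotic efflux kinetics, Hill dose-response, quadratic
# lipophilicity-activity with group offsets); they do not simulate
# membrane physics.

#' Simulate a chloride-efflux trace
#'
#' Generates `y(t) = a - b * c^t` plus additive Gaussian noise: chloride
#' release rising asymptotically from `a - b` at t = 0 towards the
#' plateau `a`.
#'
#' @param a Plateau, %.
#' @param b Amplitude, % (positive).
#' @param c Decay base per second, in (0, 1).
#' @param duration_s Trace length in seconds (default 300, the assay
#'   window); must be at least `10 * dt`.
#' @param dt Sampling interval, seconds.
#' @param noise_sd Gaussian noise standard deviation, %.
#' @param loading Carrier loading the trace represents, mol% (metadata).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed) and does not disturb the caller's RNG state.
#' @return An `efflux_trace` `data.frame`: `time_s`, `efflux_pct`, with
#'   `loading` and `truth` attributes.
#' @export
simulate_trace <- function(a, b, c, duration_s = 300, dt = 3,
                           noise_sd = 0, loading = 0.05, seed = NULL) {
  if (!is.finite(c) || c <= 0 || c >= 1) {
    stop("c must lie strictly in (0, 1)", call. = FALSE)
  }
  if (b <= 0) stop("b must be positive", call. = FALSE)
  if (duration_s < 10 * dt) {
    stop("duration must be at least 10 sampling intervals", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  times <- seq(0, duration_s, by = dt)
  y <- a - b * c^times
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(times), 0, noise_sd))
  }
  structure(data.frame(time_s = times, efflux_pct = y),
            loading = loading,
            truth = list(a = a, b = b, c = c, kini = -b * log(c)),
            class = c("efflux_trace", "data.frame"))
}

#' Simulate a Hill dose-response series
#'
#' Responses follow `100 * x^n / (ec50^n + x^n)` plus additive Gaussian
#' noise, the model inverted by [fit_hill()].
#'
#' @param ec50 True EC50, mol% (positive).
#' @param hill_n True Hill cooperativity (positive).
#' @param loadings Carrier loadings to evaluate, mol% (non-empty,
#'   positive).
#' @param noise_sd Gaussian noise standard deviation, %.
#' @param seed Integer seed (pure-function semantics as in
#'   [simulate_trace()]).
#' @return A `data.frame`: `loading_molpct`, `efflux_pct`, with a `truth`
#'   attribute.
#' @export
simulate_dose_response <- function(ec50, hill_n, loadings, noise_sd = 0,
                                   seed = NULL) {
  if (ec50 <= 0 || hill_n <= 0) {
    stop("ec50 and hill_n must be positive", call. = FALSE)
  }
  if (!length(loadings)) stop("loadings must be non-empty", call. = FALSE)
  if (any(loadings <= 0)) stop("loadings must be positive", call. = FALSE)
  stopifnot(noise_sd >= 0)
  y <- 100 * loadings^hill_n / (ec50^hill_n + loadings^hill_n)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(loadings), 0, noise_sd))
  }
  structure(data.frame(loading_molpct = loadings, efflux_pct = y),
            truth = list(ec50 = ec50, hill_n = hill_n),
            class = "data.frame")
}

# Stratified log P draw: allocates compounds to the low/mid/high bands in
# roughly the 8/25/10 proportions of the measured library, then samples
# uniformly within each band (intersected with logp_range).
.draw_logp <- function(n, logp_range) {
  cuts <- c(2.5, 5)
  lo <- logp_range[1]; hi <- logp_range[2]
  if (lo >= cuts[1] || hi <= cuts[2]) return(runif(n, lo, hi))
  props <- c(8, 25, 10) / 43
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) counts[2] <- counts[2] + rem
  bands <- rbind(c(lo, cuts[1]), c(cuts[1], cuts[2]), c(cuts[2], hi))
  unlist(lapply(1:3, function(i) runif(counts[i], bands[i, 1],
                                       bands[i, 2])), use.names = FALSE)
}

#' Simulate a compound library with a planted parabolic QSAR
#'
#' Generates a compound table whose potency follows
#' `log10(1/EC50) = intercept + linear * logP + quad * logP^2
#' (+ group offset) + N(0, noise_sd)` with log P drawn across
#' `logp_range`, stratified into low/mid/high bands echoing the design of
#' the measured library; EC50 is the back-transform, so noise is additive
#' on the modelled (log-potency) scale. A descriptor matrix is emitted
#' containing the true `alogps` column plus decoy descriptors drawn as
#' standard normals rescaled to plausible descriptor ranges, uncorrelated
#' with the response by construction. Defaults mirror the scale of the
#' measured 43-compound dataset (coefficients near -0.58 / 1.2 / -0.13,
#' residual noise ~0.45 log units).
#'
#' Auxiliary columns are generated consistently with the assay structure:
#' Hill n uniform in 0.85-1.75, k_ini tied to EC50 through a log-log
#' relation with mild noise, and retention time affine in log P.
#'
#' @param n_compounds Library size (>= 6).
#' @param intercept,linear,quad True quadratic coefficients on the
#'   log-potency scale.
#' @param group_offsets Optional named vector of per-group intercept
#'   shifts; compounds are assigned to groups in round-robin order. NULL
#'   for an ungrouped library.
#' @param logp_range Log P interval to cover (default `c(1, 7.5)`).
#' @param noise_sd Response noise, log10 units.
#' @param n_decoys Number of decoy descriptor columns.
#' @param seed Integer seed.
#' @return A list: `table` (`compound_table`, with a `group` column when
#'   `group_offsets` is given), `descriptors` (`descriptor_matrix`:
#'   `alogps` + decoys), `truth` (list of all planted parameters,
#'   per-compound log P, group assignment and noiseless response).
#' @export
simulate_library <- function(n_compounds = 43, intercept = -0.58,
                             linear = 1.2, quad = -0.13,
                             group_offsets = NULL,
                             logp_range = c(1, 7.5), noise_sd = 0.45,
                             n_decoys = 5, seed = NULL) {
  if (n_compounds < 6) stop("need at least 6 compounds", call. = FALSE)
  stopifnot(noise_sd >= 0, diff(logp_range) > 0, n_decoys >= 0)
  with_seed(seed, {
    logp <- sort(.draw_logp(n_compounds, logp_range))
    if (!is.null(group_offsets)) {
      if (is.null(names(group_offsets))) {
        names(group_offsets) <- paste0("g", seq_along(group_offsets))
      }
      grp <- rep(names(group_offsets),
                 length.out = n_compounds)[sample.int(n_compounds)]
      off <- group_offsets[grp]
    } else {
      grp <- NULL
      off <- 0
    }
    y_true <- intercept + linear * logp + quad * logp^2 + off
    y <- y_true + rnorm(n_compounds, 0, noise_sd)
    ec50 <- 10^(-y)
    hill_n <- runif(n_compounds, 0.85, 1.75)
    kini <- 10^(-1.95 - 1.05 * log10(ec50) +
                  rnorm(n_compounds, 0, 0.05)) / 10
    rt <- 6 + 1.1 * logp + rnorm(n_compounds, 0, 0.3)
    tab <- data.frame(
      compound_id = sprintf("S%03d", seq_len(n_compounds)),
      ec50_molpct = ec50, hill_n = hill_n, kini_pct_per_s = kini,
      alogps = logp, rt_min = rt,
      r4 = NA_character_, r5 = NA_character_, r6_class = NA_character_,
      ec50_imputed = FALSE, stringsAsFactors = FALSE)
    if (!is.null(grp)) tab$group <- grp
    attr(tab, "provenance") <- "simulate_library"
    class(tab) <- c("compound_table", "data.frame")
    desc <- data.frame(alogps = logp)
    if (n_decoys > 0) {
      for (j in seq_len(n_decoys)) {
        scale <- 10^runif(1, -1, 2)
        center <- runif(1, -10, 100)
        desc[[sprintf("decoy_%02d", j)]] <-
          rnorm(n_compounds) * scale + center
      }
    }
    list(table = tab,
         descriptors = descriptor_matrix(desc, tab$compound_id),
         truth = list(intercept = intercept, linear = linear, quad = quad,
                      group_offsets = group_offsets, noise_sd = noise_sd,
                      logp = logp, group = grp, log_potency_true = y_true,
                      seed = seed))
  })
}
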