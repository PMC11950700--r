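#' Specification of a synthetic cohort
#'
#' Describes a seeded synthetic cohort with the statistical structure
#' the 2-stage selector assumes: a minority-class binary outcome driven
#' by a logistic model over a few planted features (linear, threshold
#' and interaction effects), redundant feature pairs, mixed
#' continuous/binary noise features, and MCAR missingness. The defaults
#' emulate the shape of the motivating cohort: about 100 records and 50
#' mixed-type features with a 0.25-prevalence outcome.
#'
#' @param n Number of records (default 102).
#' @param n_continuous Continuous features including planted and
#'   redundant columns (default 35).
#' @param n_binary Binary noise features (default 15).
#' @param planted Data.frame with columns `name`, `type` (`"linear"`,
#'   `"threshold"` or `"interaction"`), `effect` (log-odds scale) and
#'   `partner` (second factor for interaction effects). The default
#'   plants 5 features with effects 1.5, 1.25, 1.0 (linear), 1.0
#'   (threshold) and 0.75 (interaction).
#' @param redundant Data.frame with columns `name`, `source`,
#'   `transform` (`"copy"`, `"affine"` or `"monotone"`) and `noise_sd`.
#' @param prevalence Target outcome prevalence in (0, 1) (default 0.25).
#' @param missing_rate MCAR missingness rate on feature cells
#'   (default 0.05).
#' @param seed Integer seed; the cohort is fully determined by it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 102, n_continuous = 35, n_binary = 15,
                        planted = default_planted(),
                        redundant = default_redundant(),
                        prevalence = 0.25, missing_rate = 0.05, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, missing_rate >= 0,
            missing_rate < 1, n >= 10)
  stopifnot(all(planted$type %in% c("linear", "threshold", "interaction")),
            all(is.finite(planted$effect)))
  reserved <- nrow(planted) + nrow(redundant)
  if (n_continuous < reserved)
    stop("n_continuous must cover the ", reserved,
         " planted and redundant features")
  if (anyDuplicated(c(planted$name, redundant$name)))
    stop("planted and redundant feature names must be disjoint")
  structure(list(n = n, n_continuous = n_continuous, n_binary = n_binary,
                 planted = planted, redundant = redundant,
                 prevalence = prevalence, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_planted <- function() {
  data.frame(
    name = c("rel_lin_a", "rel_lin_b", "rel_lin_c", "rel_thresh", "rel_inter"),
    type = c("linear", "linear", "linear", "threshold", "interaction"),
    effect = c(1.5, 1.25, 1.0, 1.0, 0.75),
    partner = c(NA, NA, NA, NA, "rel_lin_a"),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_redundant <- function() {
  data.frame(name = c("red_copy", "red_affine"),
             source = c("noise_c01", "noise_c02"),
             transform = c("copy", "affine"),
             noise_sd = c(0.005, 0.01),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws continuous features from mixed Gaussian/log-normal marginals
#' and binary features from Bernoulli distributions, then draws the
#' outcome from a logistic model over the planted features: linear
#' terms, indicator (threshold-at-0) effects, and products of two
#' planted features for the nonlinear interaction effects. The
#' intercept is solved numerically so the expected prevalence matches
#' the specification. Redundant columns are derived from their source
#' columns plus Gaussian noise, and MCAR missingness is applied to
#' feature cells. The same seed always yields the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `table` (data.frame incl. `id` and `outcome`
#'   columns), `schema` ([feature_schema()]), `outcome` (column name)
#'   and `truth` (planted set, redundant pairs, generating
#'   coefficients).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  planted <- spec$planted
  redundant <- spec$redundant
  n_noise <- spec$n_continuous - nrow(planted) - nrow(redundant)
  noise_names <- sprintf("noise_c%02d", seq_len(n_noise))
  bin_names <- sprintf("noise_b%02d", seq_len(spec$n_binary))

  withr::with_seed(spec$seed, {
    cols <- list()
    for (nm in planted$name) cols[[nm]] <- stats::rnorm(n)
    for (i in seq_along(noise_names)) {
      cols[[noise_names[i]]] <- if (i %% 2 == 0) {
        exp(stats::rnorm(n, sd = 0.5))  # right-skewed marginal
      } else stats::rnorm(n)
    }
    for (nm in bin_names) {
      p <- stats::runif(1, 0.2, 0.8)
      cols[[nm]] <- stats::rbinom(n, 1, p)
    }

    eta <- rep(0, n)
    for (i in seq_len(nrow(planted))) {
      x <- cols[[planted$name[i]]]
      eta <- eta + switch(planted$type[i],
        linear = planted$effect[i] * x,
        threshold = planted$effect[i] * as.numeric(x > 0),
        interaction = {
          partner <- planted$partner[i]
          if (is.na(partner) || is.null(cols[[partner]]))
            stop("interaction effect '", planted$name[i],
                 "' needs an existing partner feature")
          planted$effect[i] * x * cols[[partner]]
        })
    }
    g <- function(b0) mean(stats::plogis(b0 + eta)) - spec$prevalence
    b0 <- stats::uniroot(g, c(-30, 30))$root
    y <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
    if (length(unique(y)) < 2)
      stop("unsatisfiable prevalence given the planted effects; ",
           "generated outcome is single-class")

    for (i in seq_len(nrow(redundant))) {
      src <- cols[[redundant$source[i]]]
      if (is.null(src))
        stop("redundant source '", redundant$source[i], "' does not exist")
      noise <- stats::rnorm(n, sd = redundant$noise_sd[i])
      cols[[redundant$name[i]]] <- switch(redundant$transform[i],
        copy = src + noise,
        affine = 1.5 * src + 0.5 + noise,
        monotone = stats::plogis(src) + noise,
        stop("unknown transform '", redundant$transform[i], "'"))
    }

    feat_names <- c(planted$name, redundant$name, noise_names, bin_names)
    tab <- as.data.frame(cols[feat_names])
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * ncol(tab)) < spec$missing_rate,
                     nrow = n)
      for (j in seq_len(ncol(tab))) tab[mask[, j], j] <- NA
    }
    tab <- cbind(id = sprintf("p%03d", seq_len(n)), tab, outcome = y)

    kinds <- c(id = "identifier",
               stats::setNames(rep("continuous",
                                   nrow(planted) + nrow(redundant) + n_noise),
                               c(planted$name, redundant$name, noise_names)),
               stats::setNames(rep("binary", spec$n_binary), bin_names),
               outcome = "outcome")
    schema <- feature_schema(kinds)
    list(table = tab, schema = schema, outcome = "outcome",
         truth = list(planted = planted, redundant = redundant,
                      intercept = b0, prevalence = mean(y)))
  })
}
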