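#' Simulation configuration for synthetic expression cohorts
#'
#' Builds a validated \linkS4class{SimulationConfig}. Defaults mirror the
#' discovery-cohort structure the analysis is designed for: a 2000-gene
#' log2 matrix over 20 IBC, 20 non-IBC and 5 normal samples; 59 planted
#' signature genes shifted by 1.5 noise-SD units in the IBC class with a
#' random sign per gene (so the signature contains both up- and
#' down-regulated blocks); receptor scores on a small ordinal grid with
#' an exact-matchable subset guaranteed by construction; validation-cohort
#' batch effects (global offset 0.5, per-gene jitter SD 0.3);
#' post-treatment attenuation 0.2; and exponential survival with a true
#' hazard ratio of 3.15 for the positive class.
#'
#' @param n_genes total number of genes.
#' @param n_per_class named per-class sample counts.
#' @param n_signal number of planted signature genes.
#' @param effect_size mean log2 shift of planted genes in the positive
#'   class, in units of \code{noise_sd}.
#' @param noise_sd per-gene noise SD on the log2 scale.
#' @param batch_shift length-2 numeric: global additive offset and
#'   per-gene jitter SD applied to validation cohorts.
#' @param attenuation multiplier in [0, 1] applied to the planted effect
#'   for post-treatment samples.
#' @param receptor_config list with \code{pairs} (two-column (ER, HER2)
#'   grid matrix), \code{probs} (sampling weights) and
#'   \code{match_fraction} (fraction of negative samples whose score pair
#'   copies a positive sample's, so an exact-matchable subset exists).
#' @param survival_config list with \code{baseline_hazard},
#'   \code{hazard_ratio} and \code{censor_rate}.
#' @param noise_family \code{"gaussian"} (default) or \code{"laplace"}
#'   for heavy-tail robustness experiments.
#' @param seed integer; generation is a pure function of the seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n_genes = 2000,
                             n_per_class = c(IBC = 20, nonIBC = 20, normal = 5),
                             n_signal = 59,
                             effect_size = 1.5,
                             noise_sd = 1.0,
                             batch_shift = c(0.5, 0.3),
                             attenuation = 0.2,
                             receptor_config = list(
                               pairs = cbind(er = c(0, 0, 1, 2, 3, 3),
                                             her2 = c(0, 3, 2, 0, 0, 1)),
                               probs = c(0.25, 0.20, 0.15, 0.15, 0.15, 0.10),
                               match_fraction = 0.9),
                             survival_config = list(baseline_hazard = 0.05,
                                                    hazard_ratio = 3.15,
                                                    censor_rate = 0.2),
                             noise_family = "gaussian",
                             seed = 1L) {
  n_per_class <- setNames(as.integer(n_per_class), names(n_per_class))
  new("SimulationConfig", n_genes = as.integer(n_genes),
      n_per_class = n_per_class, n_signal = as.integer(n_signal),
      effect_size = as.numeric(effect_size), noise_sd = as.numeric(noise_sd),
      batch_shift = as.numeric(batch_shift),
      attenuation = as.numeric(attenuation),
      receptor_config = receptor_config, survival_config = survival_config,
      noise_family = noise_family, seed = as.integer(seed))
}

.rnoise <- function(n, sd, family) {
  if (family == "laplace") {
    # Laplace with the requested SD: scale b = sd / sqrt(2)
    u <- runif(n) - 0.5
    -sd / sqrt(2) * sign(u) * log(1 - 2 * abs(u))
  } else rnorm(n, 0, sd)
}

.draw_receptors <- function(cfg, labels) {
  rc <- cfg@receptor_config
  pairs <- rc$pairs
  idx <- sample.int(nrow(pairs), length(labels), replace = TRUE,
                    prob = rc$probs)
  er <- pairs[idx, 1]; her2 <- pairs[idx, 2]
  # guarantee an exact-matchable subset: a match_fraction share of the
  # negative class copies score pairs from positive samples
  pos <- which(labels == "IBC"); neg <- which(labels == "nonIBC")
  if (length(pos) && length(neg) && !is.null(rc$match_fraction)) {
    n_copy <- floor(rc$match_fraction * min(length(pos), length(neg)))
    if (n_copy > 0) {
      src <- sample(pos, n_copy)
      dst <- sample(neg, n_copy)
      er[dst] <- er[src]; her2[dst] <- her2[src]
    }
  }
  data.frame(er_score = er, her2_score = her2)
}

.build_matrix <- function(cfg, truth_baseline, truth_sign, planted, labels,
                          sample_ids, effect_mult = 1, batch = FALSE) {
  G <- cfg@n_genes; S <- length(labels)
  m <- matrix(truth_baseline, G, S) +
    matrix(.rnoise(G * S, cfg@noise_sd, cfg@noise_family), G, S)
  shift <- cfg@effect_size * cfg@noise_sd * effect_mult
  ibc <- labels == "IBC"
  if (any(ibc) && shift != 0) {
    pl <- match(planted, names(truth_baseline))
    m[pl, ibc] <- m[pl, ibc] + truth_sign * shift
  }
  if (batch) {
    m <- m + cfg@batch_shift[1] +
      matrix(rnorm(G, 0, cfg@batch_shift[2]), G, S)
  }
  dimnames(m) <- list(names(truth_baseline), sample_ids)
  m
}

#' Simulate a discovery cohort with a planted signature
#'
#' Background genes are drawn i.i.d. around per-gene baselines with
#' Gaussian (or optionally Laplace) noise, identically across classes.
#' Each planted gene receives a mean shift of
#' \code{effect_size * noise_sd} in the IBC class, with a random sign per
#' gene so the planted signature is bidirectional; normal-class samples
#' carry no shift. Receptor scores are drawn from the configured grid
#' with an exact-matchable subset guaranteed. Generation is a pure
#' function of \code{cfg@seed}.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a list with elements \code{cohort}
#'   (\linkS4class{ExpressionCohort}) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @examples
#' sim <- simulateCohort(simulationConfig(n_genes = 200, seed = 7))
#' table(classLabels(sim$cohort))
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  with_seed(cfg@seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg@n_genes))
    baseline <- setNames(rnorm(cfg@n_genes, 7, 1.5), gene_ids)
    planted <- sort(sample(gene_ids, cfg@n_signal))
    sgn <- setNames(sample(c(-1, 1), cfg@n_signal, replace = TRUE), planted)
    labels <- rep(names(cfg@n_per_class), cfg@n_per_class)
    sample_ids <- sprintf("S%03d", seq_along(labels))
    m <- .build_matrix(cfg, baseline, sgn, planted, labels, sample_ids)
    rec <- .draw_receptors(cfg, labels)
    ann <- data.frame(sample_id = sample_ids, class_label = labels,
                      er_score = rec$er_score, her2_score = rec$her2_score,
                      treatment = "pre", stringsAsFactors = FALSE)
    truth <- new("SimulationTruth", planted_genes = planted,
                 planted_sign = sgn, baseline = baseline,
                 true_class = setNames(labels, sample_ids),
                 true_hazard_ratio = cfg@survival_config$hazard_ratio)
    list(cohort = ExpressionCohort(m, ann), truth = truth)
  })
}

#' Simulate an independent validation cohort
#'
#' Draws a fresh cohort carrying the same planted genes and effect
#' directions as a prior discovery simulation, with a batch effect
#' (global additive offset plus per-gene jitter) applied to all values.
#' In \code{mode = "post"} the planted effect is multiplied by
#' \code{cfg@attenuation}, emulating the loss of signature signal after
#' chemotherapy. Default cohort sizes follow the pre-treatment
#' (33 IBC / 28 non-IBC) and post-treatment (13 IBC / 35 non-IBC)
#' validation settings.
#'
#' @param cfg a \linkS4class{SimulationConfig} (the discovery config).
#' @param truth the \linkS4class{SimulationTruth} from [simulateCohort()].
#' @param mode \code{"pre"} or \code{"post"} treatment.
#' @param n_per_class optional named counts overriding the mode default.
#' @param seed optional integer; defaults to a sub-seed derived from
#'   \code{cfg@seed} and the mode, so validation draws are independent of
#'   the discovery draw yet reproducible.
#' @return an \linkS4class{ExpressionCohort}.
#' @export
simulateValidationCohort <- function(cfg, truth, mode = c("pre", "post"),
                                     n_per_class = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(truth, "SimulationTruth"))
  validObject(cfg)
  if (is.null(n_per_class))
    n_per_class <- if (mode == "pre") c(IBC = 33, nonIBC = 28)
                   else c(IBC = 13, nonIBC = 35)
  if (is.null(seed))
    seed <- derive_seed(cfg@seed, if (mode == "pre") 101L else 202L)
  effect_mult <- if (mode == "post") cfg@attenuation else 1
  with_seed(seed, {
    labels <- rep(names(n_per_class), n_per_class)
    sample_ids <- sprintf("V%s%03d", toupper(substr(mode, 1, 1)),
                          seq_along(labels))
    m <- .build_matrix(cfg, truth@baseline, truth@planted_sign,
                       truth@planted_genes, labels, sample_ids,
                       effect_mult = effect_mult, batch = TRUE)
    rec <- .draw_receptors(cfg, labels)
    ann <- data.frame(sample_id = sample_ids, class_label = labels,
                      er_score = rec$er_score, her2_score = rec$her2_score,
                      treatment = mode, stringsAsFactors = FALSE)
    ExpressionCohort(m, ann)
  })
}

#' Simulate survival outcomes with a class-dependent hazard
#'
#' Event times are exponential with hazard \code{baseline_hazard} for the
#' negative class and \code{baseline_hazard * hazard_ratio} for the
#' positive class. Independently, each subject is censored with
#' probability \code{censor_rate}; a censored subject's follow-up ends at
#' a uniform time before its (unobserved) event. A pure function of
#' \code{seed}.
#'
#' @param labels per-sample class labels (named character); the positive
#'   class is \code{positive}, every other label is grouped as negative.
#' @param cfg a \linkS4class{SimulationConfig} (its
#'   \code{survival_config} is used).
#' @param positive label of the high-hazard class.
#' @param seed integer; defaults to a sub-seed of \code{cfg@seed}.
#' @return a \linkS4class{SurvivalTable} with groups
#'   \code{positive} / \code{"other"}.
#' @export
simulateSurvival <- function(labels, cfg, positive = "IBC", seed = NULL) {
  validObject(cfg)
  sc <- cfg@survival_config
  if (is.null(sc$hazard_ratio) || sc$hazard_ratio <= 0)
    stop("hazard_ratio must be positive")
  if (is.null(seed)) seed <- derive_seed(cfg@seed, 303L)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(labels))
  with_seed(seed, {
    hz <- ifelse(labels == positive,
                 sc$baseline_hazard * sc$hazard_ratio, sc$baseline_hazard)
    t_event <- rexp(length(labels), rate = hz)
    censored <- runif(length(labels)) < sc$censor_rate
    time <- ifelse(censored, runif(length(labels)) * t_event, t_event)
    survivalTable(sample_ids = ids, time = time,
                  event = as.numeric(!censored),
                  group = ifelse(labels == positive, positive, "other"))
  })
}
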