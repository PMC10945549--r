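# Synthetic screens with planted ground truth.
#
# The generative model mirrors the regression being fitted: each cytokine's
# level (fraction of the LPS-only control) is linear in the residual kinase
# activities, y = b0 + (X/100) %*% beta + noise, with a small set of planted
# kinases per cytokine carrying positive coefficients and b0 = 1 - sum(beta)
# so that a no-drug pseudo-row (all residual activity 100) sits at the control
# level 1. Responses are clipped at 0.

#' Configuration for a synthetic kinase-inhibitor screen
#'
#' Defaults mirror the screen this package models: 34 screened inhibitors, a
#' 427-inhibitor prediction panel, 298 profiled kinases and 37 secreted
#' factors. Each drug strongly inhibits (residual activity < 50) a random
#' kinase subset of expected size `selectivity * n_kinases`; each cytokine has
#' exactly `k_planted` regulating kinases with coefficients drawn
#' Uniform(0.05, 0.3) on the fraction-of-control scale.
#'
#' @param n_screen_drugs,n_panel_drugs,n_kinases,n_cytokines dimensions.
#' @param k_planted planted regulating kinases per cytokine (0 for a null
#'   screen).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   response (fraction-of-control scale).
#' @param selectivity mean fraction of kinases strongly inhibited per drug,
#'   in (0, 1].
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_screen_drugs = 34, n_panel_drugs = 427,
                       n_kinases = 298, n_cytokines = 37, k_planted = 5,
                       noise_sd = 0.02, selectivity = 0.15, seed = 1) {
  counts <- c(n_screen_drugs = n_screen_drugs, n_panel_drugs = n_panel_drugs,
              n_kinases = n_kinases, n_cytokines = n_cytokines)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("configuration error: all dimensions must be integers >= 1",
         call. = FALSE)
  if (k_planted < 0 || k_planted != round(k_planted))
    stop("configuration error: k_planted must be a non-negative integer",
         call. = FALSE)
  if (k_planted > n_kinases)
    stop("configuration error: k_planted exceeds n_kinases", call. = FALSE)
  if (noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  if (selectivity <= 0 || selectivity > 1)
    stop("configuration error: selectivity must be in (0, 1]", call. = FALSE)
  structure(list(n_screen_drugs = as.integer(n_screen_drugs),
                 n_panel_drugs = as.integer(n_panel_drugs),
                 n_kinases = as.integer(n_kinases),
                 n_cytokines = as.integer(n_cytokines),
                 k_planted = as.integer(k_planted), noise_sd = noise_sd,
                 selectivity = selectivity, seed = as.integer(seed)),
            class = "sim_config")
}

.kinase_ids <- function(p) sprintf("K%03d", seq_len(p))
.cytokine_ids <- function(m) sprintf("CYT%02d", seq_len(m))

#' Simulate a drug-by-kinase residual-activity matrix
#'
#' Entries are the percent of uninhibited kinase activity remaining in the
#' presence of each drug (0 = fully inhibited, 100 = untouched). Strongly
#' inhibited entries are Uniform(`0`, `inhibited_max`); the rest sit near 100
#' with Normal(100, `jitter_sd`) jitter truncated to `[0, 100]`.
#'
#' @param cfg a [sim_config()].
#' @param n_drugs number of drugs (default: the screen size in `cfg`).
#' @param drug_prefix row-name prefix.
#' @param inhibited_max upper residual activity of strongly inhibited entries.
#' @param jitter_sd assay jitter of uninhibited entries.
#' @param seed seed set before drawing; `NULL` to continue the current RNG
#'   stream (used by [simulate_screen()]).
#' @return Numeric matrix `n_drugs` x `n_kinases`, entries in `[0, 100]`.
#' @export
simulate_drug_target_matrix <- function(cfg, n_drugs = cfg$n_screen_drugs,
                                        drug_prefix = "drug",
                                        inhibited_max = 50, jitter_sd = 2,
                                        seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_drugs)
  p <- cfg$n_kinases
  if (n < 1) stop("configuration error: n_drugs must be >= 1", call. = FALSE)
  hit <- matrix(stats::runif(n * p) < cfg$selectivity, n, p)
  X <- matrix(pmin(pmax(stats::rnorm(n * p, 100, jitter_sd), 0), 100), n, p)
  X[hit] <- stats::runif(sum(hit), 0, inhibited_max)
  dimnames(X) <- list(sprintf("%s%03d", drug_prefix, seq_len(n)),
                      .kinase_ids(p))
  X
}

#' Simulate planted kinase-to-cytokine ground truth
#'
#' Per cytokine, exactly `k_planted` kinases receive positive coefficients
#' drawn Uniform(0.05, 0.3); all other coefficients are exactly zero. The
#' intercept is `1 - sum(coefficients)` so the uninhibited (LPS-only) level is
#' exactly 1 on the fraction-of-control scale.
#'
#' @inheritParams simulate_drug_target_matrix
#' @return An object of class `"kir_ground_truth"`: `coefficients` (kinase x
#'   cytokine matrix), `intercepts` (per cytokine) and `support` (list of
#'   planted kinase ids per cytokine).
#' @export
simulate_ground_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- cfg$n_kinases; m <- cfg$n_cytokines
  beta <- matrix(0, p, m, dimnames = list(.kinase_ids(p), .cytokine_ids(m)))
  for (c in seq_len(m)) {
    if (cfg$k_planted == 0) next
    planted <- sample.int(p, cfg$k_planted)
    beta[planted, c] <- stats::runif(cfg$k_planted, 0.05, 0.3)
  }
  structure(list(coefficients = beta,
                 intercepts = setNames(1 - colSums(beta), colnames(beta)),
                 support = apply(beta, 2, function(b)
                   rownames(beta)[b > 0], simplify = FALSE)),
            class = "kir_ground_truth")
}

.check_gt_x <- function(X, gt) {
  if (ncol(X) != nrow(gt$coefficients))
    stop("shape error: X has ", ncol(X), " kinases but the ground truth has ",
         nrow(gt$coefficients), call. = FALSE)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), rownames(gt$coefficients)))
    stop("shape error: kinase ids of X and ground truth do not match",
         call. = FALSE)
  invisible(TRUE)
}

#' Noiseless response levels implied by a ground truth
#'
#' `level = b0 + (X/100) %*% beta`, clipped at 0: the expected
#' fraction-of-control level of each cytokine under each drug.
#'
#' @param X residual-activity matrix (drugs x kinases).
#' @param gt a [simulate_ground_truth()] result.
#' @return Matrix drugs x cytokines.
#' @export
true_response_levels <- function(X, gt) {
  stopifnot(inherits(gt, "kir_ground_truth"))
  .check_gt_x(X, gt)
  lev <- sweep((X / 100) %*% gt$coefficients, 2L, gt$intercepts, "+")
  pmax(lev, 0)
}

#' Simulate screen responses under a planted ground truth
#'
#' `y = b0 + (X/100) %*% beta + eps`, `eps ~ Normal(0, noise_sd^2)`, clipped
#' at 0. A no-drug pseudo-row (all residual activity 100) yields the LPS-only
#' control level `b0 + sum(beta) = 1` on average.
#'
#' @inheritParams true_response_levels
#' @inheritParams simulate_drug_target_matrix
#' @return Matrix drugs x cytokines of responses on the fraction-of-control
#'   scale.
#' @export
simulate_responses <- function(X, gt, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gt, "kir_ground_truth"))
  .check_gt_x(X, gt)
  if (!is.null(seed)) set.seed(seed)
  mu <- sweep((X / 100) %*% gt$coefficients, 2L, gt$intercepts, "+")
  y <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                   nrow(mu), ncol(mu))
  y <- pmax(y, 0)
  dimnames(y) <- list(rownames(X), colnames(gt$coefficients))
  y
}

#' Simulate a complete in-silico screen
#'
#' One seeded draw of everything the pipeline consumes: the screened
#' drug-target matrix, the larger prediction panel, the planted ground truth,
#' and the screen responses. Identical config gives byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @return List with `config`, `x_screen`, `x_panel`, `ground_truth`,
#'   `y_screen`.
#' @examples
#' sim <- simulate_screen(sim_config(n_screen_drugs = 10, n_kinases = 12,
#'                                   n_cytokines = 2, k_planted = 2, seed = 7))
#' dim(sim$x_screen)
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  x_screen <- simulate_drug_target_matrix(cfg, seed = NULL)
  x_panel <- simulate_drug_target_matrix(cfg, n_drugs = cfg$n_panel_drugs,
                                         drug_prefix = "panel", seed = NULL)
  gt <- simulate_ground_truth(cfg, seed = NULL)
  y_screen <- simulate_responses(x_screen, gt, cfg, seed = NULL)
  list(config = cfg, x_screen = x_screen, x_panel = x_panel,
       ground_truth = gt, y_screen = y_screen)
}

#' Simulate a replicate secretome table (control vs stimulus)
#'
#' Long-format replicate readouts for a control-versus-LPS comparison:
#' per-factor baselines are log-normal, `n_changed` factors shift by
#' `fold_change` under the stimulus (`n_down` of them downward), and replicate
#' noise is log-normal with log-scale standard deviation `sigma`.
#'
#' @param n_factors number of secreted factors (default 191).
#' @param n_changed number of truly shifted factors (default 34).
#' @param n_down how many of the shifted factors go down rather than up.
#' @param fold_change true fold change of shifted factors.
#' @param n_replicates replicates per condition.
#' @param sigma log-scale replicate noise sd.
#' @param seed integer seed.
#' @return `data.frame(factor, condition, replicate, value)` with conditions
#'   `"control"` and `"LPS"`, plus attribute `"changed"` naming the truly
#'   shifted factors (sign-annotated: `"up"`/`"down"`).
#' @export
simulate_secretome <- function(n_factors = 191, n_changed = 34, n_down = 2,
                               fold_change = 4, n_replicates = 4,
                               sigma = 0.1, seed = 1) {
  if (n_changed > n_factors || n_down > n_changed)
    stop("configuration error: n_down <= n_changed <= n_factors required",
         call. = FALSE)
  if (n_replicates < 2)
    stop("configuration error: at least 2 replicates per condition",
         call. = FALSE)
  set.seed(seed)
  ids <- sprintf("F%03d", seq_len(n_factors))
  baseline <- stats::rlnorm(n_factors, meanlog = log(100), sdlog = 1)
  fc <- rep(1, n_factors)
  changed <- sample.int(n_factors, n_changed)
  dirn <- rep("up", n_changed)
  if (n_down > 0) dirn[seq_len(n_down)] <- "down"
  fc[changed] <- ifelse(dirn == "down", 1 / fold_change, fold_change)
  grid <- expand.grid(factor = ids, condition = c("control", "LPS"),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- baseline[match(grid$factor, ids)]
  mu <- ifelse(grid$condition == "LPS", mu * fc[match(grid$factor, ids)], mu)
  grid$value <- mu * exp(stats::rnorm(nrow(grid), 0, sigma))
  attr(grid, "changed") <- setNames(dirn, ids[changed])
  grid
}

#' Write a planted ground truth to disk
#'
#' Coefficients (with the intercept as a final `"(intercept)"` row) go to a
#' tab-separated file; the per-cytokine support lists and intercepts go to
#' JSON.
#'
#' @param gt a `"kir_ground_truth"`.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(gt, "kir_ground_truth"))
  if (!is.null(tsv_path)) {
    tab <- rbind(gt$coefficients, "(intercept)" = gt$intercepts)
    write_matrix(tab, tsv_path, id_name = "kinase")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(intercepts = as.list(gt$intercepts),
                              support = gt$support),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
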