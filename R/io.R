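# Readers, writers, configuration and the end-to-end pipeline.

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a matrix with an id column and a header row
#'
#' Expects tab- or comma-separated text (by extension) with kinase/cytokine
#' ids in the header and drug ids in the first column. Duplicate ids, missing
#' cells and non-numeric cells are rejected with the offending row and column
#' named.
#'
#' @param path input file.
#' @param sep field separator; default from the extension.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .sep_for(path)
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop(path, ": expected an id column plus data columns",
                          call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop(path, ": duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  colids <- names(raw)[-1]
  if (anyDuplicated(colids))
    stop(path, ": duplicate column id(s): ",
         paste(unique(colids[duplicated(colids)]), collapse = ", "),
         call. = FALSE)
  chr <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": missing or non-numeric cell at row '", ids[bad[1, 1]],
         "', column '", colids[bad[1, 2]], "'", call. = FALSE)
  dimnames(num) <- list(ids, colids)
  num
}

#' @describeIn read_matrix Residual-activity matrix: additionally requires all
#'   entries to be finite and `>= 0` (percent of uninhibited control).
#' @export
read_drug_target_matrix <- function(path, sep = NULL) {
  x <- read_matrix(path, sep)
  if (any(x < 0))
    stop(path, ": residual activities must be >= 0", call. = FALSE)
  x
}

#' @describeIn read_matrix Response table: levels relative to the LPS-only
#'   control, required `>= 0`.
#' @export
read_response_table <- function(path, sep = NULL) {
  x <- read_matrix(path, sep)
  if (any(x < 0))
    stop(path, ": normalized responses must be >= 0", call. = FALSE)
  x
}

#' Write a matrix with an id column and header row
#'
#' Inverse of [read_matrix()]; values survive a round trip to better than
#' 1e-12 relative precision.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file; separator from the extension.
#' @param id_name header of the id column.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- .sep_for(path)
  df <- data.frame(rownames(x),
                   apply(x, 2, function(col) sprintf("%.15g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_name, colnames(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format secretome replicate table
#'
#' @param path tab-separated file with header columns `factor`, `condition`,
#'   `replicate`, `value`.
#' @return A validated data frame.
#' @export
read_secretome_table <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  .check_secretome(raw)
  raw
}

#' Read a drug annotation table
#'
#' @param path tab-separated file with at least columns `drug_id` and
#'   `fda_approved` (logical or 0/1).
#' @return Data frame with `fda_approved` coerced to logical.
#' @export
read_drug_annotations <- function(path) {
  ann <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "fda_approved") %in% names(ann)))
    stop(path, ": needs columns drug_id and fda_approved", call. = FALSE)
  ann$fda_approved <- as.logical(ann$fda_approved) |
    (!is.na(suppressWarnings(as.numeric(ann$fda_approved))) &
       suppressWarnings(as.numeric(ann$fda_approved)) > 0)
  ann
}

# Deterministic 32-bit polynomial hash of a string (for the run manifest).
.config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' All analysis thresholds live here, never hard-coded in the stages. Paths
#' may be `NULL` to disable the corresponding stage (`secretome` disables the
#' differential stage, `network` the network stage); `x_panel` is required
#' when `predict = TRUE`.
#'
#' @param x_screen,y_screen paths to the screen drug-target matrix and
#'   response table (required).
#' @param x_panel path to the prediction-panel drug-target matrix.
#' @param secretome path to a long-format replicate secretome table.
#' @param annotations path to a drug annotation table.
#' @param network path to a reference interaction edge list.
#' @param out_dir output directory.
#' @param selection cytokines of interest (default: all modeled).
#' @param alpha_grid,nlambda,lambda_min_ratio regression grid parameters.
#' @param nrmse_threshold,pearson_threshold model quality gate.
#' @param inhibition_threshold percent efficacy at which a cytokine counts as
#'   affected.
#' @param fdr differential-secretion significance level.
#' @param top_k size of the ranked top-drug table.
#' @param max_hops,prune_threshold network extraction parameters
#'   (`prune_threshold = NULL` keeps all extracted edges).
#' @param predict run the out-of-panel prediction stage.
#' @param seed integer seed recorded in the manifest.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(x_screen, y_screen, x_panel = NULL,
                            secretome = NULL, annotations = NULL,
                            network = NULL, out_dir = "kir_output",
                            selection = NULL,
                            alpha_grid = seq(0, 1, by = 0.1), nlambda = 100,
                            lambda_min_ratio = 1e-3, nrmse_threshold = 0.1,
                            pearson_threshold = 0.85,
                            inhibition_threshold = 50, fdr = 0.05,
                            top_k = 10, max_hops = 2, prune_threshold = NULL,
                            predict = TRUE, seed = 1) {
  if (nrmse_threshold <= 0 || pearson_threshold < -1 || pearson_threshold > 1)
    stop("configuration error: invalid quality thresholds", call. = FALSE)
  if (inhibition_threshold <= 0 || inhibition_threshold > 100)
    stop("configuration error: inhibition_threshold must be in (0, 100]",
         call. = FALSE)
  if (fdr <= 0 || fdr >= 1)
    stop("configuration error: fdr must be in (0, 1)", call. = FALSE)
  structure(list(x_screen = x_screen, y_screen = y_screen, x_panel = x_panel,
                 secretome = secretome, annotations = annotations,
                 network = network, out_dir = out_dir, selection = selection,
                 alpha_grid = alpha_grid, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 nrmse_threshold = nrmse_threshold,
                 pearson_threshold = pearson_threshold,
                 inhibition_threshold = inhibition_threshold, fdr = fdr,
                 top_k = top_k, max_hops = max_hops,
                 prune_threshold = prune_threshold, predict = predict,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Comma-separated
#' values for `alpha_grid` and `selection`; `TRUE`/`FALSE` for `predict`;
#' numbers are parsed, everything else stays a string.
#'
#' @param path configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3) stop("cannot parse config line: ", m[1], call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    args[[key]] <- switch(key,
      alpha_grid = as.numeric(strsplit(val, ",")[[1]]),
      selection = trimws(strsplit(val, ",")[[1]]),
      predict = toupper(val) %in% c("TRUE", "1", "YES"),
      {
        num <- suppressWarnings(as.numeric(val))
        if (!is.na(num)) num else val
      })
  }
  do.call(pipeline_config, args)
}

#' Write a per-cytokine model report as JSON
#'
#' @param model a `"kir_model"`.
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
write_model_report <- function(model, path) {
  stopifnot(inherits(model, "kir_model"))
  best <- .best_solution(model)
  nz <- best$coefficients[best$coefficients != 0]
  report <- list(
    cytokine = model$cytokine_id,
    alpha_grid = model$alpha_grid,
    solutions = lapply(model$solutions, function(s)
      list(alpha = s$alpha, lambda = s$lambda, loocv_mse = s$loocv_mse,
           n_nonzero = sum(s$coefficients != 0))),
    best_alpha = model$best_alpha,
    intercept = best$intercept,
    coefficients = as.list(nz),
    quality = list(nrmse = model$quality$nrmse,
                   pearson_r = model$quality$pearson_r,
                   accepted = model$quality$accepted,
                   reason = model$quality$reason),
    informative_kinases = model$informative_kinases)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

.flat_predictions <- function(pred) {
  data.frame(drug = rep(rownames(pred), times = ncol(pred)),
             cytokine = rep(colnames(pred), each = nrow(pred)),
             predicted_level = as.vector(pred), stringsAsFactors = FALSE)
}

#' Run the full KiR pipeline
#'
#' Chains the stages: differential secretion (optional), per-cytokine model
#' fitting, out-of-panel prediction, efficacy and drug ranking, the
#' kinase-cytokine hit matrix, and cytokine subnetwork extraction (optional).
#' All outputs are written under `cfg$out_dir` in a fixed layout, and a
#' `manifest.json` records the package version, configuration (with a hash),
#' seed and per-stage outputs, so identical configurations rerun to identical
#' outputs. Any stage failure aborts with the stage name and cause.
#'
#' @param cfg a [pipeline_config()] or path to a key-value config file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  for (key in c("x_screen", "y_screen", "x_panel", "secretome", "annotations",
                "network")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("configuration error: ", key, " file not found: ", p,
           call. = FALSE)
  }
  if (cfg$predict && is.null(cfg$x_panel))
    stop("configuration error: x_panel is required when predict = TRUE",
         call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list(package = "kirscreen",
                   version = as.character(utils::packageVersion("kirscreen")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   # hash covers the analysis settings, not the output path
                   config_hash = .config_hash(paste(deparse(
                     unclass(cfg)[setdiff(names(cfg), "out_dir")]),
                     collapse = "")),
                   stages = list())

  if (!is.null(cfg$secretome)) {
    diff <- stage("diff", {
      raw <- read_secretome_table(cfg$secretome)
      differential_secretion(raw, fdr = cfg$fdr)
    })
    write.table(diff, out("differential.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$diff <- list(output = "differential.tsv",
                                 n_tested = sum(!is.na(diff$p)),
                                 n_significant = sum(diff$significant))
  }

  fits <- stage("fit", {
    X <- read_drug_target_matrix(cfg$x_screen)
    Y <- read_response_table(cfg$y_screen)
    if (!setequal(rownames(X), rownames(Y)))
      stop("screen drug ids of x_screen and y_screen differ")
    Y <- Y[rownames(X), , drop = FALSE]
    fit_kir_models(X, Y, alpha_grid = cfg$alpha_grid, nlambda = cfg$nlambda,
                   lambda_min_ratio = cfg$lambda_min_ratio,
                   nrmse_threshold = cfg$nrmse_threshold,
                   pearson_threshold = cfg$pearson_threshold)
  })
  dir.create(out("models"), showWarnings = FALSE)
  for (cy in names(fits$models))
    write_model_report(fits$models[[cy]], out("models", paste0(cy, ".json")))
  fit_summary <- summary(fits)
  write.table(fit_summary, out("model_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$fit <- list(
    output = c("model_summary.tsv", "models/"),
    n_fitted = length(fits$models),
    n_accepted = sum(fit_summary$accepted),
    skipped = fits$skipped)

  if (cfg$predict) {
    pred <- stage("predict", {
      X_panel <- read_drug_target_matrix(cfg$x_panel)
      predict_out_of_panel(fits, X_panel, accepted_only = TRUE)
    })
    write.table(.flat_predictions(pred), out("predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$predict <- list(output = "predictions.tsv",
                                    n_drugs = nrow(pred),
                                    n_cytokines = ncol(pred))

    rank_out <- stage("rank", {
      eff <- compute_efficacy(pred)
      selection <- cfg$selection %||% colnames(eff)
      ann <- if (!is.null(cfg$annotations))
        read_drug_annotations(cfg$annotations) else NULL
      X_panel <- read_drug_target_matrix(cfg$x_panel)
      list(eff = eff,
           ranking = rank_drugs(eff, selection, k = cfg$top_k,
                                inhibition_threshold =
                                  cfg$inhibition_threshold,
                                annotations = ann, X_panel = X_panel))
    })
    write_matrix(rank_out$eff, out("efficacy.tsv"), id_name = "drug")
    write.table(rank_out$ranking$table, out("drug_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    profiles <- lapply(rank_out$ranking$top$drug_id, function(d)
      efficacy_profile(rank_out$eff, d))
    names(profiles) <- rank_out$ranking$top$drug_id
    jsonlite::write_json(profiles, out("top_drug_profiles.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    manifest$stages$rank <- list(
      output = c("efficacy.tsv", "drug_ranking.tsv",
                 "top_drug_profiles.json"),
      inhibition_threshold = cfg$inhibition_threshold,
      top_drugs = rank_out$ranking$top$drug_id)
  }

  km <- stage("kinase_matrix", {
    sel <- cfg$selection
    if (!is.null(sel)) sel <- intersect(sel, names(accepted_models(fits)))
    if (!is.null(sel) && !length(sel)) sel <- NULL
    build_kinase_cytokine_matrix(fits, selection = sel)
  })
  write_matrix(km$matrix, out("kinase_cytokine_matrix.tsv"),
               id_name = "kinase")
  write.table(km$counts, out("kinase_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$kinase_matrix <- list(
    output = c("kinase_cytokine_matrix.tsv", "kinase_counts.tsv"),
    n_informative = sum(rowSums(km$matrix) > 0))

  if (!is.null(cfg$network)) {
    nets <- stage("network", {
      net <- load_reference_network(cfg$network)
      dir.create(out("networks"), showWarnings = FALSE)
      done <- character(0)
      for (cy in names(accepted_models(fits))) {
        if (!cy %in% igraph::V(net)$name) next
        sub <- extract_cytokine_network(
          net, cy, fits$models[[cy]]$informative_kinases,
          max_hops = cfg$max_hops)
        if (!is.null(cfg$prune_threshold))
          sub <- prune_by_weight(sub, cfg$prune_threshold)
        write_network_graphml(sub, out("networks", paste0(cy, ".graphml")))
        network_to_json(sub, out("networks", paste0(cy, ".json")))
        done <- c(done, cy)
      }
      done
    })
    manifest$stages$network <- list(output = "networks/",
                                    cytokines = nets)
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(manifest)
}
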