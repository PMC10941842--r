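# Configuration, delimited-text I/O and the staged pipeline.
#
# All artifacts are plain delimited text: matrices here are small (hundreds
# of rows by dozens of columns) and text keeps every stage inspectable and
# language-portable. Every output file starts with provenance comment lines
# (tool version, config hash, seed) so a result can always be traced to the
# configuration that produced it; numeric content is deterministic under a
# fixed config, so reruns are byte-identical.

#' Default pipeline configuration
#'
#' The full nested parameter set of the pipeline, with defaults matching the
#' standard analysis: a 20-TR (40 s at TR = 2 s) rectangle convolved with a
#' sigma = 3 Gaussian truncated at 7 TRs, K = 5 states, fuzziness and seed
#' grids for FPC selection, 30 permutation repeats, alpha = 0.05, and
#' 10-fold nested cross-validation.
#'
#' @return nested named list (see the methods vignette for the meaning and
#'   units of each field).
#' @export
default_config <- function() {
  list(
    paths = list(output_dir = "fuzzyconn_out", manifest = NULL,
                 covariates = NULL),
    window = list(rect_len = 20L, sigma = 3, truncation = 7L, step = 1L,
                  tr = 2),
    simulate = list(n_group0 = 160L, n_group1 = 151L, T_win = 124L, C = 7L,
                    separation = 1.5, noise_sd = 0.1, smoothness = 10,
                    concentration = 0.5, n_sites = 7L, target_state = 1L,
                    occupancy_effect = 0, transition_effect = 0,
                    symptom_effect = 0, seed = 0L),
    clustering = list(K = 5L, m_grid = c(1.1, 1.3, 1.5, 1.7, 2, 2.5),
                      seed_grid = 0:9, tol = 1e-6, max_iter = 1000L),
    explain = list(repeats = 30L, eps = 1e-12, seed = 0L),
    inference = list(alpha = 0.05, var_equal = TRUE,
                     score_name = "panss_neg"),
    classify = list(folds = 10L, inner_folds = 5L, seed = 0L)
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations are single YAML documents mirroring
#' \code{\link{default_config}}. Reading fills unspecified fields with
#' defaults and rejects unknown keys.
#'
#' @param path YAML file path.
#' @param config configuration list to write.
#' @return \code{read_config}: the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user, prefix = character(0))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(def, user, prefix) {
  if (is.null(user)) return(def)
  extra <- setdiff(names(user), names(def))
  if (length(extra))
    stop("config: unknown key(s): ",
         paste(paste(c(prefix, ""), collapse = "."), extra, sep = "",
               collapse = ", "))
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      def[[nm]] <- merge_config(def[[nm]], user[[nm]], c(prefix, nm))
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

# Polynomial rolling hash of the serialized config: a short stable
# provenance token (not cryptographic). Paths are excluded so that the same
# analysis parameters hash identically wherever the output lives.
config_hash <- function(config) {
  config$paths <- NULL
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(config)),
                                      collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(config) {
  c(paste0("# fuzzyconn ",
           as.character(utils::packageVersion("fuzzyconn"))),
    paste0("# config_hash=", config_hash(config),
           " seed=", config$simulate$seed))
}

#' Write / read a delimited table with provenance header
#'
#' Tab-separated text; writer prepends \code{#}-comment provenance lines,
#' reader skips them.
#'
#' @param x data frame or matrix.
#' @param path file path.
#' @param config configuration used for the provenance header (NULL = no
#'   header).
#' @param row_col optional name under which row names are written as the
#'   first column.
#' @return \code{read_table_prov}: a data frame.
#' @export
write_table_prov <- function(x, path, config = NULL, row_col = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_header(config), con)
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(row_col))
    df <- cbind(stats::setNames(data.frame(rownames(x),
                                           stringsAsFactors = FALSE),
                                row_col), df)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_prov
#' @export
read_table_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read one subject's dFNC series
#'
#' Windows-by-pairs tab-separated text with pair labels (\code{IC<i>/IC<j>})
#' as the header.
#'
#' @param series a \code{dfnc_series} object.
#' @param path file path.
#' @param config provenance configuration.
#' @param subject_id id stored on the series when reading.
#' @export
write_dfnc_series <- function(series, path, config = NULL) {
  write_table_prov(series$values, path, config)
}

#' @rdname write_dfnc_series
#' @export
read_dfnc_series <- function(path, subject_id = NULL) {
  df <- read_table_prov(path)
  vals <- as.matrix(df)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(subject_id = subject_id, values = vals,
                 pair_labels = colnames(vals), window = NULL,
                 step = NA_integer_),
            class = "dfnc_series")
}

# Append a line to the run log (timings live here, never in numeric outputs).
log_stage <- function(outdir, config, stage, t0) {
  line <- sprintf("%s\tstage=%s\tconfig_hash=%s\telapsed=%.2fs",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  config_hash(config),
                  as.numeric(proc.time()["elapsed"]) - t0)
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

stage_start <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  as.numeric(proc.time()["elapsed"])
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the `", producer,
         "` stage first", call. = FALSE)
  path
}

# --- stages ----------------------------------------------------------------

#' Pipeline stages
#'
#' Each stage reads its upstream artifacts from \code{config$paths$output_dir},
#' writes its outputs there as tab-separated text with provenance headers,
#' and appends to \code{run.log}. \code{run_pipeline} executes the full
#' sequence: simulate, cluster, explain, features, stats, classify, regress.
#' (\code{stage_extract} converts component time-series input to dFNC and is
#' used when the input is raw time series rather than simulated dFNC.)
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @return each stage invisibly returns its main in-memory product;
#'   \code{run_pipeline} returns the list of all stage products.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_simulate <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  s <- config$simulate
  cohort <- generate_cohort(n_group0 = s$n_group0, n_group1 = s$n_group1,
                            effect_spec = list(occupancy = s$occupancy_effect,
                                               transition = s$transition_effect,
                                               symptom = s$symptom_effect),
                            T_win = s$T_win, K = config$clustering$K,
                            C = s$C, separation = s$separation,
                            noise_sd = s$noise_sd, smoothness = s$smoothness,
                            concentration = s$concentration,
                            n_sites = s$n_sites,
                            target_state = s$target_state, seed = s$seed)
  dir.create(file.path(outdir, "dfnc"), showWarnings = FALSE)
  paths <- vapply(cohort$dfnc, function(d) {
    p <- file.path(outdir, "dfnc", paste0(d$subject_id, ".tsv"))
    write_dfnc_series(d, p, config)
    p
  }, character(1))
  manifest <- data.frame(subject_id = cohort$covariates$subject_id,
                         path = file.path("dfnc",
                                          paste0(cohort$covariates$subject_id,
                                                 ".tsv")),
                         stringsAsFactors = FALSE)
  write_table_prov(manifest, file.path(outdir, "manifest.tsv"), config)
  write_table_prov(cohort$covariates, file.path(outdir, "covariates.tsv"),
                   config)
  write_table_prov(cohort$centroids,
                   file.path(outdir, "true_centroids.tsv"), config)
  log_stage(outdir, config, "simulate", t0)
  invisible(cohort)
}

#' @rdname stages
#' @param manifest data frame (\code{subject_id}, \code{path}) pointing at
#'   frames-by-components time-series files; defaults to
#'   \code{config$paths$manifest}.
#' @export
stage_extract <- function(config, manifest = NULL) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  if (is.null(manifest)) {
    mp <- require_artifact(config$paths$manifest, "simulate")
    manifest <- read_table_prov(mp)
  }
  w <- config$window
  win <- make_tapered_window(w$rect_len, w$sigma, w$truncation)
  dir.create(file.path(outdir, "dfnc"), showWarnings = FALSE)
  series <- lapply(seq_len(nrow(manifest)), function(i) {
    ts <- as.matrix(read_table_prov(manifest$path[i]))
    d <- extract_dfnc(ts, win, step = w$step,
                      subject_id = manifest$subject_id[i])
    write_dfnc_series(d, file.path(outdir, "dfnc",
                                   paste0(d$subject_id, ".tsv")), config)
    d
  })
  out_manifest <- data.frame(subject_id = manifest$subject_id,
                             path = file.path("dfnc",
                                              paste0(manifest$subject_id,
                                                     ".tsv")),
                             stringsAsFactors = FALSE)
  write_table_prov(out_manifest, file.path(outdir, "manifest.tsv"), config)
  log_stage(outdir, config, "extract", t0)
  invisible(series)
}

# Read all subjects' dFNC listed in the output-dir manifest; returns list of
# dfnc_series.
load_dfnc <- function(config) {
  outdir <- config$paths$output_dir
  mp <- require_artifact(file.path(outdir, "manifest.tsv"), "simulate")
  manifest <- read_table_prov(mp)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(outdir, manifest$path[i])
    read_dfnc_series(require_artifact(p, "simulate"),
                     subject_id = manifest$subject_id[i])
  })
}

#' @rdname stages
#' @export
stage_cluster <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  series <- load_dfnc(config)
  X <- do.call(rbind, lapply(series, `[[`, "values"))
  cl <- config$clustering
  model <- fcm_select(X, K = cl$K, m_grid = cl$m_grid,
                      seed_grid = cl$seed_grid, tol = cl$tol,
                      max_iter = cl$max_iter)
  write_table_prov(model$centroids, file.path(outdir, "model_centroids.tsv"),
                   config)
  write_table_prov(model$grid, file.path(outdir, "model_grid.tsv"), config)
  yaml::write_yaml(list(K = model$K, m = model$m, seed = model$seed,
                        fpc = model$fpc, n_iter = model$n_iter,
                        converged = model$converged),
                   file.path(outdir, "model_meta.yaml"))
  dir.create(file.path(outdir, "memberships"), showWarnings = FALSE)
  offset <- 0L
  for (d in series) {
    Tn <- nrow(d$values)
    U <- model$memberships[offset + seq_len(Tn), , drop = FALSE]
    colnames(U) <- paste0("state", seq_len(model$K))
    write_table_prov(U, file.path(outdir, "memberships",
                                  paste0(d$subject_id, ".tsv")), config)
    offset <- offset + Tn
  }
  log_stage(outdir, config, "cluster", t0)
  invisible(model)
}

# Rebuild the fitted model and pooled data from stage outputs.
load_model <- function(config) {
  outdir <- config$paths$output_dir
  meta <- yaml::read_yaml(require_artifact(file.path(outdir,
                                                     "model_meta.yaml"),
                                           "cluster"))
  centroids <- as.matrix(read_table_prov(
    require_artifact(file.path(outdir, "model_centroids.tsv"), "cluster")))
  series <- load_dfnc(config)
  X <- do.call(rbind, lapply(series, `[[`, "values"))
  U <- membership_update(sq_dist(X, centroids), meta$m)
  model <- structure(list(centroids = centroids, memberships = U,
                          m = meta$m, K = as.integer(meta$K),
                          fpc = meta$fpc, objective = NULL,
                          n_iter = meta$n_iter, converged = meta$converged,
                          seed = meta$seed, call = NULL),
                     class = "fcm")
  subject <- rep(vapply(series, `[[`, character(1), "subject_id"),
                 vapply(series, function(d) nrow(d$values), integer(1)))
  list(model = model, X = X, subject = subject, series = series)
}

#' @rdname stages
#' @export
stage_explain <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  lm_ <- load_model(config)
  ex <- config$explain
  g <- g2pc(lm_$X, lm_$model, repeats = ex$repeats, seed = ex$seed)
  p <- p2d(lm_$X, lm_$model, repeats = ex$repeats, seed = ex$seed,
           eps = ex$eps)
  tab <- data.frame(feature = colnames(g),
                    g2pc_mean = colMeans(g),
                    g2pc_sd = apply(g, 2, stats::sd),
                    gp2d_total = unname(p$gp2d_total),
                    gp2d_median = unname(p$gp2d_median),
                    lp2d_mean = colMeans(p$lp2d),
                    pct_nonzero_lp2d = unname(pct_nonzero_lp2d(p)),
                    stringsAsFactors = FALSE)
  write_table_prov(tab, file.path(outdir, "importance_table.tsv"), config)
  write_table_prov(g, file.path(outdir, "importance_g2pc.tsv"), config)
  lp <- data.frame(subject_id = lm_$subject, p$lp2d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_prov(lp, file.path(outdir, "lp2d.tsv"), config)
  log_stage(outdir, config, "explain", t0)
  invisible(list(g2pc = g, p2d = p, table = tab))
}

#' @rdname stages
#' @export
stage_features <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  mdir <- require_artifact(file.path(outdir, "memberships"), "cluster")
  files <- list.files(mdir, full.names = TRUE)
  ids <- sub("\\.tsv$", "", basename(files))
  memberships <- stats::setNames(lapply(files, function(f)
    as.matrix(read_table_prov(f))), ids)
  lp_path <- file.path(outdir, "lp2d.tsv")
  lp2d <- NULL; subject <- NULL
  if (file.exists(lp_path)) {
    lp <- read_table_prov(lp_path)
    subject <- lp$subject_id
    lp2d <- as.matrix(lp[, -1, drop = FALSE])
  }
  cov_path <- file.path(outdir, "covariates.tsv")
  covariates <- if (file.exists(cov_path)) read_table_prov(cov_path) else NULL
  # keep manifest order (covariates order), not alphabetical file order
  if (!is.null(covariates))
    memberships <- memberships[covariates$subject_id]
  ft <- feature_table(memberships, lp2d = lp2d, subject = subject,
                      covariates = covariates, eps = config$explain$eps)
  write_table_prov(ft, file.path(outdir, "features.tsv"), config)
  fam <- attr(ft, "families")
  write_table_prov(data.frame(feature = names(fam), family = unname(fam),
                              stringsAsFactors = FALSE),
                   file.path(outdir, "feature_families.tsv"), config)
  log_stage(outdir, config, "features", t0)
  invisible(ft)
}

load_features <- function(config) {
  outdir <- config$paths$output_dir
  ft <- read_table_prov(require_artifact(file.path(outdir, "features.tsv"),
                                         "features"))
  fam <- read_table_prov(require_artifact(file.path(outdir,
                                                    "feature_families.tsv"),
                                          "features"))
  attr(ft, "families") <- stats::setNames(fam$family, fam$feature)
  ft
}

#' @rdname stages
#' @export
stage_stats <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  ft <- load_features(config)
  res <- run_family_tests(ft, alpha = config$inference$alpha,
                          var_equal = config$inference$var_equal)
  write_table_prov(res, file.path(outdir, "stats_group.tsv"), config)
  log_stage(outdir, config, "stats", t0)
  invisible(res)
}

#' @rdname stages
#' @export
stage_regress <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  ft <- load_features(config)
  res <- symptom_regression(ft, score_name = config$inference$score_name,
                            alpha = config$inference$alpha)
  write_table_prov(res, file.path(outdir, "stats_regression.tsv"), config)
  log_stage(outdir, config, "regress", t0)
  invisible(res)
}

#' @rdname stages
#' @export
stage_classify <- function(config) {
  outdir <- config$paths$output_dir
  t0 <- stage_start(outdir)
  ft <- load_features(config)
  cl <- config$classify
  reports <- classify_families(ft, folds = cl$folds,
                               inner_folds = cl$inner_folds, seed = cl$seed)
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(family = r$family, auc_mean = r$auc_mean, auc_sd = r$auc_sd,
               sens_mean = r$sens_mean, sens_sd = r$sens_sd,
               spec_mean = r$spec_mean, spec_sd = r$spec_sd,
               stringsAsFactors = FALSE)))
  write_table_prov(tab, file.path(outdir, "classifier_report.tsv"), config)
  coefs <- do.call(rbind, lapply(reports, function(r) {
    cr <- coefficient_report(r)
    cr$family <- r$family
    cr
  }))
  write_table_prov(coefs, file.path(outdir, "classifier_coefficients.tsv"),
                   config)
  log_stage(outdir, config, "classify", t0)
  invisible(reports)
}

#' @rdname stages
#' @export
run_pipeline <- function(config = default_config()) {
  cohort <- stage_simulate(config)
  model <- stage_cluster(config)
  expl <- stage_explain(config)
  ft <- stage_features(config)
  stats_res <- stage_stats(config)
  reports <- stage_classify(config)
  regress <- stage_regress(config)
  invisible(list(cohort = cohort, model = model, explain = expl,
                 features = ft, stats = stats_res, classify = reports,
                 regress = regress))
}
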