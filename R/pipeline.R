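## End-to-end orchestration: features -> fit/predict -> deuterate ->
## evaluate, driven by a JSON (or in-memory list) configuration, with a
## run manifest recording inputs, seed and parameters for reproducibility.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

validate_config <- function(config) {
  for (key in c("pdb", "annotations", "peptides")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("validation error: config file '", key, "' does not exist: ",
           config[[key]])
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  invisible(config)
}

#' Run the full prediction pipeline
#'
#' Executes the configured stages in order and writes all artifacts plus a
#' manifest under `config$out_dir`. Stages:
#' \describe{
#'   \item{simulate}{`config$simulate = list(n, sigma)`: generate a
#'     synthetic feature/logPF table from the coefficient preset instead of
#'     reading a structure.}
#'   \item{features}{`config$pdb` + `config$annotations`: extract burial,
#'     secondary-structure and hydrogen-bond covariates
#'     (`config$features = list(radius, scope, include_het)`).}
#'   \item{fit}{`config$fit = list(alpha, elimination)`: refit the
#'     log-linear model to the measured logPFs; otherwise the
#'     `"poppet-2018"` preset (or `config$coefficients`, a JSON file) is
#'     used.}
#'   \item{predict}{always: predicted logPF per residue.}
#'   \item{deuterate}{`config$peptides` + `config$sequence`: theoretical
#'     uptake profiles on the configured time grid
#'     (`config$times = list(n_points, t_min, t_max)`), for measured and
#'     predicted PFs.}
#'   \item{evaluate}{when measured logPFs are available: accuracy report.}
#' }
#' Outputs are byte-identical for identical config, inputs and seed.
#'
#' @param config Path to a JSON configuration file, or an equivalent list.
#' @return Invisibly, a list with the manifest and the main in-memory
#'   results (`features`, `coefs`, `predicted`, `profiles`, `report`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(read_config(config))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  outputs <- character(0)
  results <- list()
  stage <- "init"
  on_fail <- function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         if (length(outputs)) paste0(" [partial outputs: ",
                                     paste(outputs, collapse = ", "), "]")
         else "", call. = FALSE)
  tryCatch({
    ## ---- features / simulate ----
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      coeffs <- poppet_coefficients()
      feats <- simulate_pf_dataset(coeffs,
                                   n = config$simulate$n %||% 200,
                                   sigma = config$simulate$sigma %||% 0.5,
                                   seed = seed)
      feats$logPF_measured <- feats$logPF
    } else {
      stage <- "features"
      structure <- if (!is.null(config$pdb)) read_pdb(config$pdb) else NULL
      ann <- read_table(config$annotations, "annotation")
      fo <- config$features %||% list()
      feats <- build_features(structure, ann,
                              radius = fo$radius %||% 6.5,
                              scope = fo$scope %||% "all-atoms",
                              include_het = isTRUE(fo$include_het))
    }
    f_path <- file.path(out_dir, "features.csv")
    utils::write.csv(feats, f_path, row.names = FALSE)
    outputs <- c(outputs, f_path)
    results$features <- feats

    ## ---- fit / coefficients ----
    stage <- "fit"
    coefs <- if (!is.null(config$fit)) {
      fit <- poppet(logPF ~ motion + ss + burial + hbond, feats,
                    alpha = config$fit$alpha %||% 0.05,
                    elimination = config$fit$elimination %||% "factor")
      fit$coefs
    } else if (!is.null(config$coefficients) &&
               file.exists(config$coefficients %||% "")) {
      tab <- jsonlite::read_json(config$coefficients, simplifyVector = TRUE)
      new_poppet_coefs(as.data.frame(tab))
    } else poppet_coefficients(config$coefficients %||% "poppet-2018")
    c_path <- file.path(out_dir, "coefficients.json")
    jsonlite::write_json(coefs$table, c_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, c_path)
    results$coefs <- coefs

    ## ---- predict ----
    stage <- "predict"
    predicted <- data.frame(chain = feats$chain, resno = feats$resno,
                            logPF = predict(coefs, feats),
                            source = "poppet", stringsAsFactors = FALSE)
    p_path <- file.path(out_dir, "pf_predicted.csv")
    write_table(predicted, p_path, "pf")
    outputs <- c(outputs, p_path)
    results$predicted <- predicted

    measured <- NULL
    if (!is.null(feats$logPF_measured) && any(!is.na(feats$logPF_measured)))
      measured <- data.frame(chain = feats$chain, resno = feats$resno,
                             logPF = feats$logPF_measured,
                             source = "measured", stringsAsFactors = FALSE)

    ## ---- deuterate ----
    if (!is.null(config$peptides) && !is.null(config$sequence)) {
      stage <- "deuterate"
      peptides <- read_table(config$peptides, "peptide")
      kin <- config$kinetics %||% list()
      ki <- intrinsic_rates(config$sequence,
                            pD = kin$pD %||% 7.0,
                            temperature = kin$temperature %||% 293.15)
      first_resno <- config$first_resno %||% 1L
      kint_table <- stats::setNames(ki, seq_along(ki) + first_resno - 1L)
      tg <- config$times %||% list()
      times <- if (!is.null(tg$explicit)) as.numeric(tg$explicit)
      else make_time_grid(tg$n_points %||% 16, tg$t_min %||% 30,
                          tg$t_max %||% 16 * 86400)
      src <- if (!is.null(measured)) measured else predicted
      err <- deuteration_error(src, predicted, peptides, kint_table, times,
                               back_exchange = config$back_exchange %||% 1)
      d_path <- file.path(out_dir, "profiles.csv")
      utils::write.csv(err, d_path, row.names = FALSE)
      outputs <- c(outputs, d_path)
      results$profiles <- err
    }

    ## ---- evaluate ----
    if (!is.null(measured)) {
      stage <- "evaluate"
      rep <- compare_logpf(measured, predicted)
      r_path <- file.path(out_dir, "report.json")
      jsonlite::write_json(
        list(n = rep$n, mean_abs = rep$mean_abs, max_abs = rep$max_abs,
             mean_signed = rep$mean_signed, pearson = rep$pearson,
             subset = rep$subset),
        r_path, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, r_path)
      results$report <- rep
    }
  }, error = on_fail)

  ## ---- manifest ----
  inputs <- unlist(config[c("pdb", "annotations", "peptides")])
  manifest <- list(
    package = "poppet",
    version = as.character(utils::packageVersion("poppet")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    output_checksums = as.list(tools::md5sum(outputs)))
  m_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, m_path, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
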