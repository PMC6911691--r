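#' Run the full screening-and-inversion pipeline
#'
#' Orchestrates preprocess -> screen -> split -> fit -> evaluate for every
#' requested parameter x screening method x model combination from a
#' single configuration, writing per-band score tables, the sample split,
#' a comparison table in the style of published model-result tables, and a
#' reproducibility manifest.
#'
#' The configuration is a named list (or path to a YAML file) with
#' optional entries:
#' \describe{
#'   \item{simulate}{list of [sim_config()] overrides; when present the
#'     input is generated synthetically.}
#'   \item{input}{list with `spectra` and `chem` file paths (used when
#'     `simulate` is absent).}
#'   \item{parameters}{parameter names (default: all in the chemistry
#'     table).}
#'   \item{methods}{screening methods (default `c("gc","vip","spa","all")`).}
#'   \item{models}{regressors (default `c("plsr","elm")`).}
#'   \item{preprocess, gc, vip}{config overrides for
#'     [preprocess_config()], [gc_config()], [vip_config()].}
#'   \item{fraction}{Kennard-Stone calibration share (default 2/3).}
#'   \item{ncomp, hidden}{hyperparameters or `"cv"` (default).}
#'   \item{seed}{integer seed (default 1).}
#' }
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return invisibly, a list with `reports` (ranked comparison
#'   data.frame), `screens`, `split`, `fits`, and `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  pre_cfg <- do.call(preprocess_config, config$preprocess %||% list())
  gc_cfg <- do.call(gc_config, config$gc %||% list())
  vip_cfg <- do.call(vip_config, config$vip %||% list())
  fraction <- config$fraction %||% (2 / 3)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- generate_spectra(do.call(sim_config, sim_args))
    spectra <- sim$spectra; chem <- sim$chem
  } else if (!is.null(config$input)) {
    spectra <- read_spectra(config$input$spectra,
                            stage = config$input$stage %||% "raw")
    chem <- read_chem(config$input$chem)
  } else stop("config needs either a 'simulate' block or 'input' paths")

  parameters <- config$parameters %||% chem$parameters
  unknown <- setdiff(parameters, chem$parameters)
  if (length(unknown) > 0)
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "))
  methods <- config$methods %||% c("gc", "vip", "spa", "all")
  models <- config$models %||% c("plsr", "elm")

  joined <- join_chem(spectra, chem)
  snv <- if (joined$spectra$stage == "snv") joined$spectra
         else preprocess_spectra(joined$spectra, pre_cfg)
  split <- split_two_thirds(snv, fraction = fraction)
  cal <- split$calibration; val <- split$validation

  screens <- list(); fits <- list(); reports <- list()
  for (param in parameters) {
    y <- chem_values(joined$chem, param)
    scr <- list()
    need_gc <- any(c("gc", "spa") %in% methods)
    need_vip <- any(c("vip", "spa") %in% methods)
    if (need_gc)
      scr$gc <- gcd_screen(y, snv, gc_cfg, parameter = param)
    if (need_vip)
      scr$vip <- vip_screen(snv, y, vip_cfg, parameter = param)
    if ("spa" %in% methods) scr$spa <- spa_screen(scr$gc, scr$vip)
    if ("pearson" %in% methods)
      scr$pearson <- pearson_screen(snv, y, parameter = param)
    if ("all" %in% methods)
      scr$all <- screen_bands(snv, y, param, "all", gc_cfg, vip_cfg)
    screens[[param]] <- scr[intersect(methods, names(scr))]
    for (method in methods) {
      sel <- select_bands(scr[[method]], snv)
      for (model in models) {
        fit <- fit_inversion(sel$x[cal, , drop = FALSE], y[cal],
                             model, config$ncomp %||% "cv",
                             config$hidden %||% "cv", seed)
        pred_val <- predict(fit$fit, sel$x[val, , drop = FALSE])
        key <- paste(param, method, model, sep = ".")
        fits[[key]] <- fit$fit
        reports[[key]] <- model_report(
          y[cal], fit$fit$fitted, y[val], pred_val,
          parameter = param, method = method, model = model,
          hyper = fit$hyper, n_bands = ncol(sel$x))
      }
    }
  }
  comparison <- compare_models(reports)

  manifest <- list(package = "specwq",
                   version = as.character(utils::packageVersion("specwq")),
                   r_version = as.character(getRversion()),
                   seed = seed, fraction = fraction,
                   parameters = parameters, methods = methods,
                   models = models,
                   n_samples = length(snv$sample_ids),
                   n_bands = length(snv$wavelengths),
                   config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (param in names(screens))
      for (method in names(screens[[param]]))
        utils::write.table(
          screen_table(screens[[param]][[method]]),
          file.path(out_dir, paste0("scores_", param, "_", method, ".tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(sample_id = c(split$calibration_ids, split$validation_ids),
                 partition = rep(c("calibration", "validation"),
                                 c(length(cal), length(val)))),
      file.path(out_dir, "split.csv"), sep = ",",
      row.names = FALSE, quote = FALSE)
    utils::write.table(comparison, file.path(out_dir, "reports.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(reports = comparison, screens = screens, split = split,
                 fits = fits, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
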