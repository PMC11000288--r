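#' Configure an end-to-end optimization run
#'
#' Collects everything [run_pipeline()] needs: the study data (defaulting to
#' the packaged protoplast study), which responses to model, whether to run
#' the response-surface and/or network model families, their settings, the
#' desirability goals and the output directory.
#'
#' @param design,response A `bbd_design` and matching response tibble;
#'   default to [load_protoplast_study()].
#' @param responses Character vector of response columns to model.
#' @param rsm Logical: fit the quadratic models, adequacy ANOVA and the
#'   desirability optimum.
#' @param ann `NULL` to skip network training, otherwise a list of
#'   [train_bpnn()] settings (`n_hidden` may be a vector, one per response).
#' @param ga `NULL` to skip the GA search over trained networks, otherwise a
#'   list of [ga_optimize()] settings.
#' @param goals Desirability goals passed to [optimize_desirability()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; propagated to split, initialization and GA.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, response = NULL,
                            responses = c("yield", "viability"),
                            rsm = TRUE,
                            ann = list(n_hidden = 18, algorithm = "lm",
                                       restarts = 8),
                            ga = list(population = 50, generations = 100),
                            goals = NULL,
                            out_dir = tempfile("protodoe_run_"),
                            seed = 0) {
  if (is.null(design) || is.null(response)) {
    study <- load_protoplast_study()
    design <- design %||% study$design
    response <- response %||% study$response
  }
  missing_cols <- setdiff(responses, names(response))
  if (length(missing_cols)) {
    rlang::abort(paste("response columns not found:", paste(missing_cols, collapse = ", ")),
                 class = "protodoe_pipeline_error")
  }
  if (!isTRUE(rsm) && is.null(ann)) {
    rlang::abort("enable at least one model family (rsm or ann)",
                 class = "protodoe_pipeline_error")
  }
  structure(list(design = design, response = response, responses = responses,
                 rsm = isTRUE(rsm), ann = ann, ga = ga, goals = goals,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full design-fit-compare-optimize pipeline
#'
#' Reproduces the study workflow on any Box-Behnken dataset: echoes the
#' design, fits the full quadratic with its ANOVA adequacy panel per
#' response, optionally trains a back-propagation network per response,
#' builds the model-comparison report, finds the desirability optimum over
#' the quadratic models and the GA optimum over each trained network, and
#' writes every number to a machine-readable `summary.json` (plus CSV/JSON
#' artifacts per stage) in the run directory. Two runs with identical
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; the parsed summary is attached
#'   as attribute `"summary"`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(ann = NULL, out_dir = tempfile())
#' run_pipeline(cfg)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    rlang::abort(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)),
                 class = "protodoe_pipeline_error")
  }
  tryCatch({
    logf("protodoe %s | seed %d", as.character(utils::packageVersion("protodoe")),
         config$seed)
    factors <- design_factors(config$design)
    summary <- list(seed = config$seed,
                    package_version = as.character(utils::packageVersion("protodoe")),
                    responses = as.list(config$responses))

    stage <- "design"
    utils::write.csv(as.data.frame(config$design),
                     file.path(config$out_dir, "design.csv"), row.names = FALSE)

    fits <- list(); nets <- list()
    comparison_inputs <- list()
    X <- design_actual_matrix(config$design)

    for (resp in config$responses) {
      y <- config$response[[resp]]
      if (config$rsm) {
        stage <- paste0("rsm:", resp)
        logf("fitting quadratic model for %s", resp)
        fit <- fit_quadratic(config$design, y, response_name = resp)
        an <- stats::anova(fit)
        fits[[resp]] <- fit
        utils::write.csv(as.data.frame(tidy(an)),
                         file.path(config$out_dir, paste0("anova_", resp, ".csv")),
                         row.names = FALSE)
        write_json_file(list(response = resp,
                             term_order = names(coef(fit, "coded")),
                             unit_space = "both",
                             coef_coded = as.list(coef(fit, "coded")),
                             coef_actual = as.list(coef(fit, "actual"))),
                        file.path(config$out_dir, paste0("rsm_model_", resp, ".json")))
        summary$rsm[[resp]] <- c(as.list(glance(an)),
                                 list(coef_actual = as.list(coef(fit, "actual"))))
        comparison_inputs[[paste0("RSM-", resp)]] <-
          list(observed = y, predicted = fit$fitted)
      }
      if (!is.null(config$ann)) {
        stage <- paste0("ann:", resp)
        logf("training network for %s", resp)
        i <- match(resp, config$responses)
        hid <- config$ann$n_hidden %||% 18
        hid <- hid[min(i, length(hid))]
        net_fit <- train_bpnn(X, y, n_hidden = hid,
                              algorithm = config$ann$algorithm %||% "lm",
                              split = config$ann$split %||% c(0.70, 0.15, 0.15),
                              max_epochs = config$ann$max_epochs %||% 1000,
                              patience = config$ann$patience %||% 6,
                              seed = config$seed,
                              restarts = config$ann$restarts %||% 8)
        nets[[resp]] <- net_fit
        utils::write.csv(as.data.frame(net_fit$history),
                         file.path(config$out_dir, paste0("history_", resp, ".csv")),
                         row.names = FALSE)
        write_json_file(list(response = resp, n_hidden = hid,
                             algorithm = net_fit$config$algorithm,
                             input_scaling = net_fit$net$input_scaling,
                             output_scaling = net_fit$net$output_scaling,
                             weights = net_fit$net$weights,
                             best_epoch = net_fit$best_epoch,
                             stop_reason = net_fit$stop_reason),
                        file.path(config$out_dir, paste0("ann_net_", resp, ".json")))
        pred <- predict(net_fit, X)
        summary$ann[[resp]] <- list(n_hidden = hid,
                                    best_epoch = net_fit$best_epoch,
                                    stop_reason = net_fit$stop_reason,
                                    all_data_R = stats::cor(y, pred))
        comparison_inputs[[paste0("ANN-", resp)]] <-
          list(observed = y, predicted = pred)
      }
    }

    stage <- "comparison"
    report <- comparison_report(comparison_inputs)
    utils::write.csv(as.data.frame(report),
                     file.path(config$out_dir, "comparison.csv"), row.names = FALSE)
    summary$comparison <- lapply(seq_len(nrow(report)), function(i) as.list(report[i, ]))

    if (config$rsm && length(fits)) {
      stage <- "optimum:rsm"
      opt <- optimize_desirability(fits, goals = config$goals, seed = config$seed)
      write_json_file(list(settings = as.list(opt$settings),
                           predicted = as.list(opt$predicted),
                           desirability = opt$desirability),
                      file.path(config$out_dir, "optimum_rsm.json"))
      summary$optimum$rsm <- list(settings = as.list(opt$settings),
                                  predicted = as.list(opt$predicted),
                                  desirability = opt$desirability)
    }
    if (!is.null(config$ann) && !is.null(config$ga)) {
      for (resp in names(nets)) {
        stage <- paste0("optimum:ann:", resp)
        net <- nets[[resp]]
        ga_res <- ga_optimize(function(x) predict(net, x),
                              bounds = factors,
                              population = config$ga$population %||% 50,
                              generations = config$ga$generations %||% 100,
                              seed = config$seed)
        write_json_file(list(settings = as.list(ga_res$par),
                             predicted = ga_res$value),
                        file.path(config$out_dir, paste0("optimum_ann_", resp, ".json")))
        summary$optimum$ann[[resp]] <- list(settings = as.list(ga_res$par),
                                            predicted = ga_res$value)
      }
    }

    stage <- "summary"
    write_json_file(summary, file.path(config$out_dir, "summary.json"))
    logf("done")
    out <- config$out_dir
    attr(out, "summary") <- summary
    invisible(out)
  }, error = on_fail)
}
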