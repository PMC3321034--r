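#' Run the full recurrence-association pipeline
#'
#' Orchestrates the analysis end to end: obtain a cohort (simulated from
#' [sim_params]-style settings, or loaded from expression/clinical TSVs),
#' score the metagene, test the rank-sum association of the long-recurrence
#' subset with exact and Monte-Carlo nulls, scan every gene, and fit the
#' Kaplan-Meier / Cox survival models. All tabular artifacts are TSV; a
#' manifest records the package version, seed and a hash of the
#' configuration, and a rerun with the same configuration and seed
#' reproduces every TSV byte for byte.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Fields: `seed` (required), `outdir` (required),
#'   `threshold_days` (default 1095), `n_perm` (default 1e5; `NULL`
#'   disables the Monte-Carlo cross-check), `stages` (character subset of
#'   `c("metagene", "ranksum", "scan", "survival")`, default all), and
#'   either `simulate` (a list of [sim_params] arguments overriding
#'   [default_gbm_like_params], e.g. `list(n_background_genes = 500)`) or
#'   `inputs` (list with `expression`, `clinical`, and optionally
#'   `signature` paths).
#' @return invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    assert_that(file.exists(config), paste0("config file not found: ", config))
    assert_that(requireNamespace("yaml", quietly = TRUE),
                "reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML file path")
  assert_that(!is.null(config$seed), "config$seed is required")
  assert_that(!is.null(config$outdir), "config$outdir is required")
  threshold <- config$threshold_days %||% 1095
  n_perm <- if ("n_perm" %in% names(config)) config$n_perm else 1e5
  stages <- config$stages %||% c("metagene", "ranksum", "scan", "survival")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  write_tsv <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", {
      overrides <- config$simulate
      if (is.character(overrides$signature))
        overrides$signature <- read_signature(overrides$signature)
      defaults <- default_gbm_like_params(seed = config$seed)
      args <- utils::modifyList(
        unclass(defaults)[setdiff(names(defaults), "seed")],
        if (is.list(overrides)) overrides else list())
      args$seed <- args$seed %||% config$seed
      simulate_cohort(do.call(sim_params, args))
    })
    expr <- cohort$expression
    clinical <- cohort$clinical
    truth <- cohort$truth
    signature <- stage("simulate", {
      s <- config$simulate$signature %||% emt_signature()
      if (is.character(s)) read_signature(s) else s
    })
    paths$expression <- stage("simulate",
      write_expression(expr, file.path(outdir, "expression.tsv")))
    paths$clinical <- stage("simulate",
      write_clinical(clinical, file.path(outdir, "clinical.tsv")))
    paths$truth <- write_tsv(
      data.frame(sample_id = names(truth$latent_activity),
                 latent_activity = unname(truth$latent_activity),
                 subtype = unname(truth$subtype)), "truth.tsv")
  } else {
    assert_that(!is.null(config$inputs),
                "config needs either 'simulate' or 'inputs'")
    expr <- stage("read_expression", {
      p <- config$inputs$expression
      assert_that(!is.null(p) && file.exists(p),
                  paste0("expression file not found: ", p %||% "<missing>"))
      fmt <- if (grepl("\\.gct$", p, ignore.case = TRUE)) "gct" else "tsv"
      read_expression(p, fmt)
    })
    clinical <- stage("read_clinical", {
      p <- config$inputs$clinical
      assert_that(!is.null(p) && file.exists(p),
                  paste0("clinical file not found: ", p %||% "<missing>"))
      read_clinical(p)
    })
    signature <- stage("read_signature", {
      p <- config$inputs$signature
      if (is.null(p)) emt_signature() else {
        assert_that(file.exists(p), paste0("signature file not found: ", p))
        read_signature(p)
      }
    })
  }

  aligned <- stage("align", align_samples(expr, clinical))
  expr <- aligned$expression
  clinical <- aligned$clinical

  scores <- NULL
  if (any(c("metagene", "ranksum", "scan", "survival") %in% stages)) {
    scores <- stage("metagene", compute_metagene(expr, signature))
    if ("metagene" %in% stages)
      paths$metagene <- write_tsv(
        data.frame(sample_id = names(scores), score = as.numeric(scores)),
        "metagene.tsv")
  }

  responders <- clinical$sample_id[clinical$responder]
  long_set <- select_long_recurrence(clinical, threshold)

  if ("ranksum" %in% stages) {
    paths$ranksum <- stage("ranksum", {
      assert_that(length(responders) >= 2, "need >= 2 responders")
      assert_that(length(long_set) >= 1,
                  "no samples beyond the recurrence threshold")
      res <- rank_sum_test(scores[responders], long_set,
                           n_perm = n_perm, seed = config$seed)
      write_tsv(data.frame(
        field = c("n", "k", "member_ranks", "rank_sum", "p_exact",
                  "p_mc", "mc_se", "n_perm", "seed"),
        value = c(res$n, res$k, paste(res$member_ranks, collapse = "+"),
                  res$rank_sum, format(res$p_exact, digits = 12),
                  format(res$p_mc %||% NA, digits = 12),
                  format(res$mc_se %||% NA, digits = 6),
                  res$n_perm %||% NA, res$seed %||% NA)), "ranksum.tsv")
    })
  }

  if ("scan" %in% stages) {
    paths$scan <- stage("scan", {
      assert_that(length(long_set) >= 1,
                  "no samples beyond the recurrence threshold")
      scan <- genome_wide_scan(expr[, responders, drop = FALSE], long_set)
      write_tsv(as.data.frame(scan), "scan.tsv")
    })
  }

  if ("survival" %in% stages) {
    stage("survival", {
      surv <- as_survival_dataset(clinical)
      split <- median_split(scores) # full cohort, then restrict
      km <- km_logrank(surv, split[surv$sample_id])
      cox <- cox_univariate(surv, scores[surv$sample_id])
      tab <- cox$terms
      tab$term[1] <- "metagene"
      tab$model <- "univariate"
      if (all(clinical$subtype != "UNKNOWN")) {
        mc <- cox_multivariate_deviation(surv, scores[surv$sample_id])
        mt <- mc$terms; mt$model <- "multivariate"
        tab <- rbind(tab, mt)
      }
      tab <- cbind(model = tab$model, tab[setdiff(names(tab), "model")])
      paths$survival <- write_tsv(tab, "survival_cox.tsv")
      paths$logrank <- write_tsv(
        data.frame(chisq = km$chisq, df = km$df, p = km$p), "logrank.tsv")
      paths$km_plot <- file.path(outdir, "km_curves.pdf")
      grDevices::pdf(paths$km_plot, width = 6, height = 5)
      graphics::plot(km$fit, col = c("navy", "firebrick"), lwd = 2,
                     xlab = "Days to tumor recurrence",
                     ylab = "Recurrence-free fraction")
      graphics::legend("topright", legend = km$groups,
                       col = c("navy", "firebrick"), lwd = 2, bty = "n")
      grDevices::dev.off()
    })
  }

  paths$manifest <- stage("manifest", {
    cfg_file <- tempfile()
    hashed <- config[setdiff(sort(names(config)), "outdir")]
    dput(hashed, file = cfg_file)
    hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    p <- file.path(outdir, "manifest.tsv")
    utils::write.table(
      data.frame(field = c("package", "version", "seed", "config_md5"),
                 value = c("mesrec",
                           as.character(utils::packageVersion("mesrec")),
                           config$seed, hash)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  invisible(paths)
}
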