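#' Default pipeline configuration
#'
#' Nested key-value structure consumed by [run_pipeline()]. Sections:
#' `inputs` (paths to a matrix, annotations, signature, edge list, protein
#' ratio table, survival table -- all optional when the `simulate` stage
#' runs), `simulate` (see [sim_config()]), `deg` (`lfc_cut` 5, `padj_cut`
#' 0.01), `score` (`mode`, `group_field`, `positive`), `survival`
#' (generator rates for simulated cohorts), `ppi` (`ratio_cut` 2, `sig_cut`
#' 20, `zd_cut` 3, `min_score`), plus top-level `seed`, `stages`.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "deg", "score", "survival", "ppi"),
    inputs = list(
      matrix = NULL, annotations = NULL, signature = NULL,
      edges = NULL, proteins = NULL, survival = NULL
    ),
    simulate = unclass(sim_config())[setdiff(names(sim_config()), "seed")],
    deg = list(lfc_cut = 5, padj_cut = 0.01),
    score = list(mode = "signed", group_field = "condition",
                 positive = NULL),
    survival = list(baseline_hazard = 0.1, beta = 1.5, censor_rate = 0.02),
    ppi = list(ratio_cut = 2, sig_cut = 20, zd_cut = 3, min_score = NULL)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys (typo protection), checks
#' types, and verifies that every referenced input file exists. Normalizing
#' an already-normalized config is a no-op.
#'
#' @param config A named list, or a path to a YAML file holding one.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "run_config")) config <- unclass(config)
  stopifnot(is.list(config))
  defaults <- default_config()
  merged <- merge_config(defaults, config, path = "")
  numeric_fields <- list(
    c("seed"), c("deg", "lfc_cut"), c("deg", "padj_cut"),
    c("ppi", "ratio_cut"), c("ppi", "sig_cut"), c("ppi", "zd_cut"),
    c("survival", "baseline_hazard"), c("survival", "beta"),
    c("survival", "censor_rate")
  )
  for (f in numeric_fields) {
    v <- merged[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L)) {
      stop("config field `", paste(f, collapse = "."),
           "` must be a single number, got: ", deparse(v))
    }
    if (!is.null(v)) merged[[f]] <- as.numeric(v)
  }
  merged$seed <- as.integer(merged$seed)
  merged$simulate <- lapply(merged$simulate, function(v) {
    if (is.numeric(v)) as.numeric(v) else v
  })
  if (merged$deg$padj_cut <= 0 || merged$deg$padj_cut > 1) {
    warning("deg.padj_cut = ", merged$deg$padj_cut, " is outside (0, 1]")
  }
  if (!merged$score$mode %in% c("signed", "sum_all")) {
    stop("score.mode must be 'signed' or 'sum_all'")
  }
  merged$stages <- as.character(unlist(merged$stages))
  bad_stage <- setdiff(merged$stages, default_config()$stages)
  if (length(bad_stage) > 0L) {
    stop("unknown stage: ", bad_stage[1L])
  }
  for (nm in names(merged$inputs)) {
    p <- merged$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for `inputs.", nm, "` does not exist: ", p)
    }
  }
  # the simulate section must itself be a valid sim_config
  do.call(sim_config, c(merged$simulate, list(seed = merged$seed)))
  structure(merged, class = "run_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key: ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown[1L]))))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]) && !is.null(user[[nm]])) {
        stop("config key `", sub("^\\.", "", paste0(path, ".", nm)),
             "` must be a section")
      }
      defaults[nm] <- list(merge_config(defaults[[nm]], user[[nm]] %||% list(),
                                        paste0(path, ".", nm)))
    } else {
      defaults[nm] <- list(user[[nm]]) # keeps explicit NULLs
    }
  }
  defaults
}

#' Synthetic end-to-end preset
#'
#' A ready-to-run configuration exercising every stage on simulated data:
#' simulate a planted-signature cohort, derive the signature by differential
#' expression (`lfc_cut = 1`, matched to the planted 2 log2-unit effect;
#' the paper-style default of 5 targets far stronger contrasts), score it,
#' stratify simulated survival by the score, and analyze a planted-hub
#' graph.
#'
#' @param seed Integer seed.
#' @return A `run_config`.
#' @export
synthetic_preset <- function(seed = 1L) {
  validate_config(list(
    seed = as.integer(seed),
    deg = list(lfc_cut = 1, padj_cut = 0.01),
    score = list(positive = "autonomous")
  ))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate -> deg -> score -> survival -> ppi), writing every intermediate
#' as a TSV under `out_dir` together with a plain-text log and a
#' `manifest.json` listing outputs with MD5 checksums. Two runs with the
#' same config and seed produce byte-identical outputs and manifests. Every
#' TSV carries a `#` header naming the package version, config hash, and
#' seed. A stage failure aborts with the stage name after persisting the
#' partial log.
#'
#' @param config A `run_config` (see [validate_config()],
#'   [synthetic_preset()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the run's key results (`report`,
#'   `logrank`, `hubs`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_path <- file.path(out_dir, "log.txt")
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  persist_log <- function() writeLines(log_lines, log_path)

  hash <- config_hash(config)
  stamp <- sprintf("# sigstep %s config=%s seed=%d",
                   as.character(utils::packageVersion("sigstep")),
                   hash, as.integer(config$seed))
  write_stamped <- function(x, name, col_names = TRUE) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    readr::write_tsv(x, path, append = TRUE, col_names = col_names,
                     progress = FALSE)
    path
  }

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      log_lines <<- c(log_lines, sprintf("stage %s: FAILED (%s)",
                                         name, conditionMessage(e)))
      persist_log()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  state <- new.env(parent = emptyenv())
  state$outputs <- character(0)
  add_output <- function(path) state$outputs <- c(state$outputs, path)
  stages <- config$stages

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- do.call(sim_config, c(config$simulate,
                                   list(seed = config$seed)))
      sim <- simulate_expression(cfg)
      state$matrix <- sim$matrix
      state$true_signature <- sim$signature
      graph <- simulate_graph(cfg)
      state$edges <- graph$edges
      state$hub_truth <- graph$hubs
      add_output(write_stamped(
        tibble::as_tibble(sim$matrix$values, rownames = "gene"),
        "expression.tsv"
      ))
      add_output(write_stamped(sim$matrix$annotations, "annotations.tsv"))
      sig_path <- file.path(out_dir, "true_signature.tsv")
      write_signature(sim$signature, sig_path)
      add_output(sig_path)
      add_output(write_stamped(graph$edges, "edges.tsv", col_names = FALSE))
      note("stage simulate: %d genes x %d samples, %d-gene planted signature, %d graph nodes",
           nrow(sim$matrix$values), ncol(sim$matrix$values),
           nrow(sim$signature), length(graph$nodes))
    })
  }

  # --- load declared inputs ------------------------------------------------
  run_stage("inputs", function() {
    inp <- config$inputs
    if (!is.null(inp$matrix)) {
      ann <- if (!is.null(inp$annotations)) read_annotations(inp$annotations)
      state$matrix <- read_expression(inp$matrix, annotations = ann)
      note("stage inputs: read %d x %d matrix from %s",
           nrow(state$matrix$values), ncol(state$matrix$values), inp$matrix)
    }
    if (!is.null(inp$signature)) {
      state$true_signature <- read_signature(inp$signature)
    }
    if (!is.null(inp$edges)) state$edges <- read_edge_list(inp$edges)
    if (!is.null(inp$survival)) {
      state$survival_input <- read_annotations(inp$survival)
    }
    if (!is.null(inp$proteins)) {
      state$protein_table <- readr::read_tsv(inp$proteins,
                                             show_col_types = FALSE,
                                             progress = FALSE)
    }
  })

  # --- deg -----------------------------------------------------------------
  if ("deg" %in% stages) {
    run_stage("deg", function() {
      if (is.null(state$matrix)) stop("no expression matrix available")
      grp <- config$score$group_field
      deg <- per_gene_test(state$matrix, grp)
      sig <- filter_degs(deg, lfc_cut = config$deg$lfc_cut,
                         padj_cut = config$deg$padj_cut, name = "derived")
      state$deg <- deg
      if (nrow(sig) > 0L) state$derived_signature <- sig
      add_output(write_stamped(deg, "deg.tsv"))
      sig_path <- file.path(out_dir, "derived_signature.tsv")
      write_signature(sig, sig_path)
      add_output(sig_path)
      note("stage deg: %d genes tested, signature of %d up / %d down at lfc>%g padj<%g",
           nrow(deg), sum(sig$direction > 0), sum(sig$direction < 0),
           config$deg$lfc_cut, config$deg$padj_cut)
    })
  }

  # --- score ---------------------------------------------------------------
  if ("score" %in% stages) {
    run_stage("score", function() {
      if (is.null(state$matrix)) stop("no expression matrix available")
      sig <- state$derived_signature %||% state$true_signature
      if (is.null(sig)) stop("no signature available")
      report <- score_and_classify(
        state$matrix, sig,
        group_field = config$score$group_field,
        positive = config$score$positive,
        mode = config$score$mode
      )
      state$report <- report
      add_output(write_stamped(tidy(report), "scores.tsv"))
      add_output(write_stamped(glance(report), "score_stats.tsv"))
      note("stage score: signature '%s', AUC = %.4f, Welch p = %.3g",
           report$signature_name, report$auc, report$p)
    })
  }

  # --- survival ------------------------------------------------------------
  if ("survival" %in% stages) {
    run_stage("survival", function() {
      if (is.null(state$report)) stop("score stage must run before survival")
      scores <- tidy(state$report)
      surv <- state$survival_input %||% simulate_survival(
        scores,
        baseline_hazard = config$survival$baseline_hazard,
        beta = config$survival$beta,
        censor_rate = config$survival$censor_rate,
        seed = config$seed + 1L
      )
      strat <- stratify_by_score(scores, surv)
      lr <- logrank(strat)
      km <- km_estimate(strat)
      state$logrank <- lr
      add_output(write_stamped(strat, "survival.tsv"))
      add_output(write_stamped(km, "km.tsv"))
      add_output(write_stamped(lr, "logrank.tsv"))
      note("stage survival: split at sthr = %.4f (%d high / %d low), log-rank p = %.3g",
           attr(strat, "sthr"), sum(strat$group == "high"),
           sum(strat$group == "low"), lr$p)
    })
  }

  # --- ppi -----------------------------------------------------------------
  if ("ppi" %in% stages) {
    run_stage("ppi", function() {
      if (is.null(state$edges)) stop("no edge list available")
      proteins <- if (!is.null(state$protein_table)) {
        filter_proteins(state$protein_table,
                        ratio_cut = config$ppi$ratio_cut,
                        sig_cut = config$ppi$sig_cut)
      } else {
        unique(c(state$edges$from, state$edges$to))
      }
      graph <- degree_zscores(build_graph(proteins, state$edges,
                                          min_score = config$ppi$min_score))
      hubs <- select_hubs(graph, zd_cut = config$ppi$zd_cut)
      state$hubs <- hubs
      add_output(write_stamped(tidy(graph), "ppi_nodes.tsv"))
      add_output(write_stamped(hubs, "ppi_hubs.tsv"))
      note("stage ppi: %d nodes, %d hub(s) at zd >= %g",
           nrow(tidy(graph)), nrow(hubs), config$ppi$zd_cut)
    })
  }

  # --- manifest ------------------------------------------------------------
  persist_log()
  files <- c(state$outputs, log_path)
  manifest <- list(
    package = "sigstep",
    version = as.character(utils::packageVersion("sigstep")),
    seed = as.integer(config$seed),
    config_hash = hash,
    stages = stages,
    files = lapply(
      stats::setNames(files, basename(files)),
      function(f) list(md5 = unname(tools::md5sum(f)),
                       bytes = unname(file.size(f)))
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(
    report = state$report,
    logrank = state$logrank,
    hubs = state$hubs,
    manifest_path = manifest_path
  ))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}
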