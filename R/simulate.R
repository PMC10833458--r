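#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. The defaults
#' define the reference simulation conditions used throughout the package's
#' tests: a planted 29-up / 3-down signature with a 2 log2-unit effect and
#' Gaussian noise of 0.5 on top of a bimodal (modes 2 and 6) expression
#' landscape, 20 samples per group, score-linked exponential survival, and
#' an Erdos-Renyi graph with planted high-degree hubs.
#'
#' @param n_genes Total number of genes (signature + background).
#' @param n_per_group Samples per group (two groups).
#' @param n_up,n_down Planted up / down signature genes (defaults 29, 3).
#' @param effect Log2 mean shift of signature genes in the positive group
#'   (default 2).
#' @param noise_sd Per-gene Gaussian noise standard deviation (default 0.5).
#' @param bimodal_frac Fraction of background genes given a two-mode
#'   high/low structure independent of group (default 0.3).
#' @param mode_low,mode_high Centers of the low and high expression modes on
#'   log2 scale (defaults 2 and 6); signature genes sit at their midpoint at
#'   baseline.
#' @param baseline_hazard,beta,censor_rate Survival generator: baseline
#'   exponential event rate, log-hazard coefficient on the standardized
#'   score, and independent exponential censoring rate.
#' @param n_background,p_background,n_hubs,hub_degree Graph generator:
#'   background node count and edge probability, number of planted hubs, and
#'   target degree per hub.
#' @param seed Integer seed; the same config yields byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_per_group = 20,
                       n_up = 29, n_down = 3,
                       effect = 2, noise_sd = 0.5,
                       bimodal_frac = 0.3,
                       mode_low = 2, mode_high = 6,
                       baseline_hazard = 0.1, beta = 1.5, censor_rate = 0.02,
                       n_background = 200, p_background = 0.05,
                       n_hubs = 3, hub_degree = 60,
                       seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_per_group = n_per_group,
    n_up = n_up, n_down = n_down,
    effect = effect, noise_sd = noise_sd,
    bimodal_frac = bimodal_frac,
    mode_low = mode_low, mode_high = mode_high,
    baseline_hazard = baseline_hazard, beta = beta,
    censor_rate = censor_rate,
    n_background = n_background, p_background = p_background,
    n_hubs = n_hubs, hub_degree = hub_degree,
    seed = seed
  )
  counts <- c("n_genes", "n_per_group", "n_background", "seed")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1) {
      stop("`", f, "` must be a positive number")
    }
  }
  for (f in c("n_up", "n_down", "n_hubs")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop("`", f, "` must be >= 0")
  }
  if (cfg$effect < 0) stop("`effect` must be >= 0")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (cfg$bimodal_frac < 0 || cfg$bimodal_frac > 1) {
    stop("`bimodal_frac` must be in [0, 1]")
  }
  if (cfg$p_background < 0 || cfg$p_background > 1) {
    stop("`p_background` must be in [0, 1]")
  }
  if (cfg$n_up + cfg$n_down > cfg$n_genes) {
    stop("n_up + n_down exceeds n_genes")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group expression matrix with a planted signature
#'
#' Signature genes shift by `+effect` (up genes) or `-effect` (down genes) in
#' the positive (`"autonomous"`) group relative to a common baseline at the
#' midpoint of the two expression modes; the control group stays at baseline.
#' Background genes carry no group information: a `bimodal_frac` subset is
#' split high/low per sample independently of group, the rest sit at a
#' gene-specific constant mean. Gaussian noise (`noise_sd`) is added
#' everywhere.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (an `expr_mat` with a `condition` annotation of
#'   `"control"` / `"autonomous"`), `signature` (the planted ground truth as
#'   a `gene_signature`), and `labels` (per-sample condition vector).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- 2L * config$n_per_group
    n_sig <- config$n_up + config$n_down
    n_bg <- config$n_genes - n_sig
    baseline <- (config$mode_low + config$mode_high) / 2

    genes <- c(
      sprintf("SIGUP%03d", seq_len(config$n_up)),
      sprintf("SIGDN%03d", seq_len(config$n_down)),
      sprintf("BG%05d", seq_len(n_bg))
    )[seq_len(config$n_genes)]
    samples <- c(
      sprintf("ctrl_%03d", seq_len(config$n_per_group)),
      sprintf("auto_%03d", seq_len(config$n_per_group))
    )
    labels <- rep(c("control", "autonomous"), each = config$n_per_group)
    is_pos <- labels == "autonomous"

    means <- matrix(0, nrow = config$n_genes, ncol = n,
                    dimnames = list(genes, samples))
    if (config$n_up > 0L) {
      means[seq_len(config$n_up), ] <- baseline
      means[seq_len(config$n_up), is_pos] <- baseline + config$effect
    }
    if (config$n_down > 0L) {
      rows <- config$n_up + seq_len(config$n_down)
      means[rows, ] <- baseline
      means[rows, is_pos] <- baseline - config$effect
    }
    if (n_bg > 0L) {
      n_bimodal <- round(config$bimodal_frac * n_bg)
      bg_rows <- n_sig + seq_len(n_bg)
      if (n_bimodal > 0L) {
        bi_rows <- bg_rows[seq_len(n_bimodal)]
        hi <- matrix(rbinom(n_bimodal * n, 1L, 0.5) == 1L,
                     nrow = n_bimodal)
        means[bi_rows, ] <- ifelse(hi, config$mode_high, config$mode_low)
      }
      if (n_bg > n_bimodal) {
        uni_rows <- bg_rows[(n_bimodal + 1L):n_bg]
        means[uni_rows, ] <- runif(length(uni_rows),
                                   config$mode_low, config$mode_high)
      }
    }
    values <- means + rnorm(length(means), sd = config$noise_sd)
    dimnames(values) <- list(genes, samples)

    annotations <- tibble::tibble(sample_id = samples, condition = labels)
    signature <- gene_signature(
      genes[seq_len(n_sig)],
      rep(c(1L, -1L), times = c(config$n_up, config$n_down)),
      name = "planted"
    )
    list(
      matrix = expression_matrix(values, annotations = annotations),
      signature = signature,
      labels = labels
    )
  })
}

#' Simulate one bimodal gene
#'
#' Draws `n_low` values around the low mode and `n_high` around the high
#' mode, the elementary step-structured series the StepMiner threshold is
#' meant to recover. Uses the current RNG state (seed outside).
#'
#' @param n_low,n_high Samples per mode.
#' @param mode_low,mode_high Mode centers (defaults 2, 6).
#' @param sd Noise standard deviation (default 0.5).
#' @return Numeric vector of length `n_low + n_high`.
#' @export
simulate_bimodal_gene <- function(n_low = 50, n_high = 50,
                                  mode_low = 2, mode_high = 6, sd = 0.5) {
  c(rnorm(n_low, mode_low, sd), rnorm(n_high, mode_high, sd))
}

#' Simulate survival times linked to a composite score
#'
#' Exponential event times with per-subject rate
#' `baseline_hazard * exp(beta * z)` where `z` is the standardized score,
#' plus independent exponential censoring; the observed time is the minimum
#' of the two and `event` records which came first.
#'
#' @param scores Tibble with `sample_id`, `score`, or a named/plain numeric
#'   vector.
#' @param baseline_hazard Baseline event rate (> 0).
#' @param beta Log-hazard increase per standard deviation of score.
#' @param censor_rate Exponential censoring rate (0 disables censoring).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A tibble: `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(scores, baseline_hazard = 0.1, beta = 1.5,
                              censor_rate = 0.02, seed = NULL) {
  if (is.data.frame(scores)) {
    ids <- scores$sample_id
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    ids <- names(scores) %||% sprintf("s%04d", seq_along(s))
  }
  if (any(!is.finite(s))) stop("scores must be finite")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop("`baseline_hazard` must be positive")
  }
  if (censor_rate < 0) stop("`censor_rate` must be >= 0")
  gen <- function() {
    sdv <- sd(s)
    z <- if (length(s) > 1L && sdv > 0) (s - mean(s)) / sdv else rep(0, length(s))
    rate <- baseline_hazard * exp(beta * z)
    t_event <- rexp(length(s), rate)
    t_cens <- if (censor_rate > 0) {
      rexp(length(s), censor_rate)
    } else {
      rep(Inf, length(s))
    }
    tibble::tibble(
      sample_id = ids,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a graph with planted hubs
#'
#' Erdos-Renyi background (`n_background` nodes, edge probability
#' `p_background`) plus `n_hubs` planted nodes each wired to `hub_degree`
#' distinct random partners among all other nodes.
#'
#' @param config A [sim_config()] (uses its `graph` fields and `seed`).
#' @return A list: `edges` (tibble `from`, `to`), `nodes` (all node ids),
#'   `hubs` (planted hub ids).
#' @export
simulate_graph <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_background + config$n_hubs
  if (config$n_hubs > 0L && config$hub_degree >= n_total) {
    stop("hub_degree must be below the total node count (", n_total, ")")
  }
  withr::with_seed(config$seed, {
    bg <- sprintf("BGN%04d", seq_len(config$n_background))
    hubs <- if (config$n_hubs > 0L) {
      sprintf("HUB%02d", seq_len(config$n_hubs))
    } else {
      character(0)
    }
    nodes <- c(bg, hubs)
    g <- igraph::sample_gnp(config$n_background, config$p_background,
                            directed = FALSE)
    bg_edges <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      from = bg[bg_edges[, 1L]],
      to = bg[bg_edges[, 2L]]
    )
    for (h in hubs) {
      partners <- sample(setdiff(nodes, h), config$hub_degree)
      edges <- dplyr::bind_rows(
        edges, tibble::tibble(from = h, to = partners)
      )
    }
    # canonical undirected form, deduplicated
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges <- dplyr::distinct(tibble::tibble(from = a, to = b))
    list(edges = edges, nodes = nodes, hubs = hubs)
  })
}
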