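# End-to-end orchestration of the analysis.

#' Pipeline configuration
#'
#' Bundles the five key model parameters -- `p_conn` (binomial
#' probability of synaptic connection), `d` (embedding dimension, `NULL`
#' for automatic profile-likelihood selection), `G` (number of sampled
#' binary graphs), `tau` (consensus chain threshold) and `c_size`
#' (minimum class size) -- plus the random-walk path budget `m`, the BIC
#' search bound `k_max` and the master `seed`. The defaults mirror the
#' full-scale reference parameterisation
#' `{p_conn = 0.15, d = 11, G = 100, tau = 0.95, c_size = 100}` except
#' that `d` defaults to automatic selection.
#'
#' @param p_conn Per-overlap connection probability, or `NULL` to select
#'   with [choose_p_conn()].
#' @param d Embedding rank override, or `NULL` for automatic selection.
#' @param G Number of binary graphs.
#' @param tau Consensus chain-equivalence threshold.
#' @param c_size Minimum class size.
#' @param m Random-walk sampled-path budget (used when the circuit is too
#'   large for exhaustive enumeration).
#' @param k_max Largest candidate GMM component count.
#' @param patience BIC early-stop patience for the per-graph GMM search
#'   (`Inf` = exhaustive; see [fit_gmm_bic()]).
#' @param seed Master seed; every stage derives its own substream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(p_conn = 0.15, d = NULL, G = 100L, tau = 0.95,
                            c_size = 100L, m = 1e5, k_max = 20L,
                            patience = Inf, seed = 1L) {
  if (!is.null(p_conn))
    check_scalar(p_conn, "p_conn", lower = 0, upper = 1, open_lower = TRUE)
  if (!is.null(d)) check_scalar(d, "d", lower = 1, integer = TRUE)
  check_scalar(G, "G", lower = 1, integer = TRUE)
  check_scalar(tau, "tau", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(c_size, "c_size", lower = 1, integer = TRUE)
  check_scalar(m, "m", lower = 1)
  check_scalar(k_max, "k_max", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(patience, "patience", lower = 1)
  structure(list(p_conn = p_conn, d = d, G = as.integer(G), tau = tau,
                 c_size = as.integer(c_size), m = m,
                 k_max = as.integer(k_max), patience = patience,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "Pipeline config: p_conn = %s, d = %s, G = %d, tau = %g, c_size = %d\n",
    if (is.null(x$p_conn)) "auto" else format(x$p_conn),
    if (is.null(x$d)) "auto" else format(x$d), x$G, x$tau, x$c_size))
  invisible(x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full connectome-to-circuit analysis
#'
#' Executes, in order: binarization (probability conversion and binary
#' ensemble sampling), per-graph spectral clustering, consensus
#' clustering, block probability estimation and circuit flooring, then --
#' unless stopped earlier via `stages` -- biomarker annotation,
#' random-walk statistics, growth analysis and hub/goodness-of-fit
#' metrics. Each source of randomness draws from a substream of the
#' master seed, so a rerun with an identical configuration reproduces the
#' result bit for bit.
#'
#' @param strengths Strength matrix (or a `synthetic_dataset`, whose
#'   metadata is then used automatically).
#' @param config A [pipeline_config()].
#' @param metadata Optional data frame with per-neuron biomarker columns
#'   (`neurotransmitter`, `birthtime`, `community`; extra columns are
#'   annotated too).
#' @param stages Run up to this stage: `"consensus"`, `"circuit"` or
#'   `"all"`.
#' @param out_dir Optional run directory; when given, every stage's
#'   outputs plus a JSON manifest of the effective configuration are
#'   written there.
#' @return Object of class `pipeline_result` with elements `p_conn`,
#'   `ensemble`, `clusterings`, `partition`, `block_probabilities`,
#'   `circuit`, `walks`, `annotation`, `growth`, `hubs`, `fit`, `config`.
#' @export
run_pipeline <- function(strengths, config = pipeline_config(),
                         metadata = NULL, stages = c("all", "circuit",
                                                     "consensus"),
                         out_dir = NULL) {
  stages <- match.arg(stages)
  if (inherits(strengths, "synthetic_dataset")) {
    if (is.null(metadata)) metadata <- strengths$metadata
    strengths <- strengths$strengths
  }
  A <- run_stage("input", as_strength_matrix(strengths))
  n <- nrow(A)
  if (!is.null(metadata) && nrow(metadata) != n)
    stopf("metadata has %d rows but the connectome has %d neurons",
          nrow(metadata), n)
  seeds <- spawn_seeds(config$seed, 4L)

  p_conn <- run_stage("p_conn",
    if (is.null(config$p_conn)) choose_p_conn(A) else config$p_conn)
  probs <- run_stage("binarize", strength_to_probability(A, p_conn))
  ensemble <- run_stage("ensemble",
    sample_binary_ensemble(probs, config$G, seed = seeds[[1]]))
  clusterings <- run_stage("cluster",
    cluster_ensemble(ensemble, d = config$d, k_max = config$k_max,
                     patience = config$patience, seed = seeds[[2]]))
  partition <- run_stage("consensus",
    consensus_cluster(clusterings, tau = config$tau, c_size = config$c_size))

  result <- structure(
    list(p_conn = p_conn, ensemble = ensemble, clusterings = clusterings,
         partition = partition, block_probabilities = NULL, circuit = NULL,
         walks = NULL, annotation = NULL, growth = NULL, hubs = NULL,
         fit = NULL, config = config),
    class = "pipeline_result")

  if (stages != "consensus" && partition$kappa > 0) {
    result$block_probabilities <- run_stage("blockmodel",
      estimate_block_probabilities(partition, ensemble))
    result$circuit <- run_stage("circuit",
      floor_to_circuit(result$block_probabilities))
  }

  if (stages == "all" && !is.null(result$circuit)) {
    if (result$circuit$kappa >= 2)
      result$walks <- run_stage("walks",
        walk_stats(result$circuit, m = config$m, seed = seeds[[3]]))
    if (!is.null(metadata)) {
      result$annotation <- run_stage("annotate", {
        conn <- partition$labels
        schemes <- c(list(connectivity = conn),
                     lapply(metadata[setdiff(names(metadata), "neuron_id")],
                            as.character))
        posteriors <- lapply(schemes[-1L], function(sc)
          posterior_table(conn, sc))
        list(schemes = names(schemes),
             posteriors = posteriors,
             dominant = lapply(posteriors, dominant_label),
             nmi = nmi_matrix(schemes))
      })
      if ("birthtime" %in% names(metadata))
        result$growth <- run_stage("growth", {
          series <- build_daily_series(partition, metadata$birthtime)
          profile <- growth_percentages(series)
          list(series = series, profile = profile,
               critical = critical_periods(profile))
        })
    }
    if (result$circuit$kappa >= 3)
      result$hubs <- run_stage("hubs", hub_report(result$circuit))
    result$fit <- run_stage("fit",
      binomial_fit_fraction(partition, ensemble,
                            result$block_probabilities))
  }

  if (!is.null(out_dir)) run_stage("write", write_run(result, out_dir, A))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  p_conn = %.3f, G = %d\n", x$p_conn, x$config$G))
  print(x$partition)
  if (!is.null(x$circuit)) print(x$circuit)
  invisible(x)
}

# Persist a pipeline run: stage outputs plus a manifest capturing the
# effective configuration, sufficient to reproduce the run.
write_run <- function(result, out_dir, strengths) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_strength_matrix(strengths, file.path(out_dir, "strengths.mtx"))
  write_partition_csv(result$partition, file.path(out_dir, "partition.csv"))
  labs <- unclass(result$clusterings)
  write.csv(as.data.frame(labs), file.path(out_dir, "clusterings.csv"),
            row.names = FALSE)
  if (!is.null(result$block_probabilities))
    write.csv(result$block_probabilities$p_hat,
              file.path(out_dir, "block_probabilities.csv"),
              row.names = FALSE)
  if (!is.null(result$circuit))
    write_circuit(result$circuit,
                  graphml_path = file.path(out_dir, "circuit.graphml"),
                  edgelist_path = file.path(out_dir, "circuit_edges.csv"))
  if (!is.null(result$walks)) {
    for (nm in c("absorption", "shortest", "driftiness"))
      write.csv(result$walks[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  cfg <- result$config
  manifest <- list(
    package = "mesocircuit",
    version = as.character(utils::packageVersion("mesocircuit")),
    parameters = list(p_conn = result$p_conn, d = cfg$d, G = cfg$G,
                      tau = cfg$tau, c_size = cfg$c_size, m = cfg$m,
                      k_max = cfg$k_max, seed = cfg$seed),
    kappa = result$partition$kappa,
    assigned_fraction = result$partition$assigned_fraction)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
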