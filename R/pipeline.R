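#' Run the full cortico-subcortical analysis pipeline
#'
#' Orchestrates the stages in the order of the analysis: subject-level
#' partial-correlation connectivity and group random-effects inference;
#' consensus community detection on the subcortical submatrix (a gamma
#' sweep over binary and weighted matrices); null-model validation of the
#' subcortical graph; whole-brain hub classification; cortico-subcortical
#' convergence statistics with FS/FD distance distributions; and the
#' targeted-attack robustness analysis on the converging organization.
#' Identical inputs, configuration and seed give an identical report.
#'
#' @param panel a [ts_panel].
#' @param parc a [parcellation] aligned with the panel's ROI labels; its
#'   `class` column separates cortical/cerebellar from subcortical nodes.
#' @param config named list overriding defaults: `alpha` (0.05),
#'   `n_discard` (100), `gammas` (0..2 by 0.1), `n_init` (1000), `tau`
#'   (0.95), `n_null` (1000), `n_attack` (10000), `bin_width` (8),
#'   `max_distance` (NULL), `fit` ("moments"), `seed` (1).
#' @return a list of class `convorg_report` with one element per stage plus
#'   the resolved configuration.
#' @export
run_pipeline <- function(panel, parc, config = list()) {
  cfg <- utils::modifyList(list(
    alpha = 0.05, n_discard = 100, gammas = seq(0, 2, by = 0.1),
    n_init = 1000, tau = 0.95, n_null = 1000, n_attack = 10000,
    bin_width = 8, max_distance = NULL, fit = "moments", seed = 1L
  ), config)
  stopifnot(identical(parc$label, panel$roi_labels))
  sub_idx <- which(parc$class == "subcortical")
  ctx_idx <- which(parc$class != "subcortical")
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[convorg] stage %-12s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  betas <- stage("fc", fit_panel_betas(panel, n_discard = cfg$n_discard))
  fc <- stage("group_rfx", group_rfx(betas, alpha = cfg$alpha))

  sub_bin <- fc$binary[sub_idx, sub_idx]
  sub_wgt <- fc$weighted[sub_idx, sub_idx]
  mx <- max(abs(sub_wgt))
  if (mx > 0) sub_wgt <- sub_wgt / mx
  communities <- stage("communities", gamma_sweep(
    sub_bin, sub_wgt, gammas = cfg$gammas, n_init = cfg$n_init,
    tau = cfg$tau, seed = cfg$seed
  ))
  sub_part <- communities$solution$partition

  validation <- stage("validate", {
    ens <- rewire_null_ensemble(sub_bin, n = cfg$n_null, seed = cfg$seed)
    null_comparison(sub_bin, ens, sub_part, alpha = 0.01)
  })

  hubs <- stage("hubs", {
    whole_part <- integer(nrow(parc))
    whole_part[sub_idx] <- sub_part
    ctx_groups <- as.integer(factor(parc$rsn[ctx_idx]))
    whole_part[ctx_idx] <- max(sub_part) + ctx_groups
    nm <- node_degree_metrics(fc$binary, whole_part, parcellation = NULL)
    cls <- classify_nodes(nm$participation, nm$wmd_z, labels = nm$label)
    list(metrics = nm, classified = cls[sub_idx, ],
         percentages = hub_type_percentages(cls[sub_idx, ]))
  })

  convergence <- stage("converge", {
    inc <- bidirectional_graph(fc$binary, ctx_idx, sub_idx)
    counts <- convergence_counts(inc)
    keep <- rowSums(inc) > 0
    out <- list(incidence = inc, counts = counts)
    if (sum(keep) >= 2) {
      pairs <- convergence_pairs(inc[keep, , drop = FALSE], parc)
      dist <- fs_fd_distributions(pairs, bin_width = cfg$bin_width,
                                  max_distance = cfg$max_distance,
                                  fit = cfg$fit)
      out$pairs <- pairs
      out$distributions <- dist
      out$paired_test <- fs_fd_paired_test(dist)
      out$network_level <- network_level_convergence(
        inc, cortical_class = setNames(parc$network_class, parc$label)[ctx_idx],
        subcortical_network = setNames(as.character(sub_part),
                                       parc$label[sub_idx])
      )
    }
    out
  })

  attack <- stage("attack", {
    cs <- converging_subgraph(fc$binary, ctx_idx, sub_idx)
    attack_analysis(cs$adjacency, cs$subcortical, n = cfg$n_attack,
                    cortical_pool = cs$cortical, seed = cfg$seed)
  })

  structure(
    list(config = cfg, connectivity = fc, communities = communities,
         validation = validation, hubs = hubs, convergence = convergence,
         attack = attack),
    class = "convorg_report"
  )
}

#' @export
print.convorg_report <- function(x, ...) {
  cat("<convorg_report>\n")
  print(x$connectivity)
  print(x$communities)
  print(x$attack)
  invisible(x)
}
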