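#' Run the full MoA-ensemble analysis end to end
#'
#' Orchestrates every stage on one input set: fit the ensemble
#' ([netmoa()]), stratify it for the indication and the adverse event
#' ([stratify_ensemble()]), form the four High/Low groups and their
#' pairwise modified Hausdorff distances, dispersions, dendrogram and MDS
#' map, extract differential biomarkers between the indication-responder
#' subgroups with low vs high adverse-event intensity, and run the RWR
#' proximity cross-check. One `seed` determines every stochastic stage;
#' rerunning with the same arguments reproduces the result exactly.
#'
#' @param network a [signed_network()].
#' @param stim a [stimulus()].
#' @param restrictions a [restriction_set()] (the indication training
#'   data).
#' @param indication,adverse_event [effector_set()]s.
#' @param n_runs,K,min_accuracy,schedule,params,allow_fewer passed to
#'   [netmoa()].
#' @param top_n,alpha,adjust biomarker parameters (defaults 200, 0.01,
#'   `"BH"`).
#' @param proximity_fraction top-fraction cut for the proximity sets
#'   (default 0.02).
#' @param seed global integer seed.
#' @param out_dir optional directory; when given, every stage artifact is
#'   written there as TSV/Newick/JSON.
#' @return list of class `netmoa_pipeline` with elements `fit`, `groups`
#'   (per phenotype), `group_distances`, `dispersions`, `dendrogram`,
#'   `mds`, `intersections`, `biomarkers`, `proximity`.
#' @export
netmoa_pipeline <- function(network, stim, restrictions,
                            indication, adverse_event,
                            n_runs = 250L, K = 200L, min_accuracy = 0.8,
                            schedule = anneal_schedule(),
                            params = propagation_params(),
                            allow_fewer = FALSE,
                            top_n = 200L, alpha = 0.01, adjust = "BH",
                            proximity_fraction = 0.02,
                            seed = 1L, out_dir = NULL) {
  fit <- netmoa(network, stim, restrictions, n_runs = n_runs, K = K,
                min_accuracy = min_accuracy, schedule = schedule,
                params = params, base_seed = seed,
                allow_fewer = allow_fewer)
  g_ind <- stratify_ensemble(fit, indication)
  g_adv <- stratify_ensemble(fit, adverse_event)
  sm <- signal_matrix(fit)
  clouds <- list()
  for (lab in c("Low", "High")) {
    clouds[[paste0(lab, "-", indication$name)]] <-
      sm[group_members(g_ind, lab), , drop = FALSE]
    clouds[[paste0(lab, "-", adverse_event$name)]] <-
      sm[group_members(g_adv, lab), , drop = FALSE]
  }
  Dg <- group_distances(clouds)
  disp <- vapply(clouds, dispersion, 0)
  dend <- group_dendrogram(Dg)
  xy <- mds_embed(sm, dims = 2L)

  inter_ll <- intersect_groups(g_ind, g_adv, "Low", "Low")
  inter_lh <- intersect_groups(g_ind, g_adv, "Low", "High")
  # biomarkers between indication responders with low vs high adverse-event
  # intensity; fall back to the plain Low/High adverse-event groups when an
  # intersection is too small to test
  if (length(inter_ll) >= 2L && length(inter_lh) >= 2L) {
    ga <- sm[inter_ll, , drop = FALSE]
    gb <- sm[inter_lh, , drop = FALSE]
    contrast <- "Low-ind&Low-adv_vs_Low-ind&High-adv"
  } else {
    ga <- clouds[[paste0("Low-", adverse_event$name)]]
    gb <- clouds[[paste0("High-", adverse_event$name)]]
    contrast <- "Low-adv_vs_High-adv"
  }
  bc <- best_classifiers(ga, gb, top_n = top_n)
  singles <- bc$proteins[bc$kind == "single"]
  recs <- differential_test(ga, gb, candidates = singles, adjust = adjust)
  kept <- differential_filter(recs, alpha = alpha)
  report <- biomarker_report(kept, bcp_sets = list(classifier = singles))

  prox_sets <- list(
    drug = top_fraction(propagate_seeds(network, names(stim)),
                        proximity_fraction),
    indication = top_fraction(
      propagate_seeds(network, names(indication$states)),
      proximity_fraction),
    adverse_event = top_fraction(
      propagate_seeds(network, names(adverse_event$states)),
      proximity_fraction)
  )
  prox <- overlap_report(report$protein, prox_sets, network$nodes)

  out <- structure(
    list(fit = fit,
         groups = list(indication = g_ind, adverse_event = g_adv),
         group_distances = Dg, dispersions = disp, dendrogram = dend,
         mds = xy,
         intersections = list(low_low = inter_ll, low_high = inter_lh),
         biomarkers = report, biomarker_contrast = contrast,
         proximity = prox, seed = as.integer(seed)),
    class = "netmoa_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.netmoa_pipeline <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  groups: %s\n",
              paste(rownames(x$group_distances), collapse = ", ")))
  cat(sprintf("  intersections: Low&Low %d, Low&High %d MoAs\n",
              length(x$intersections$low_low),
              length(x$intersections$low_high)))
  cat(sprintf("  differential biomarkers (%s): %d\n",
              x$biomarker_contrast, nrow(x$biomarkers)))
  cat(sprintf("  proximity overlap: %d of %d biomarkers (p = %.3g)\n",
              x$proximity$count, nrow(x$biomarkers), x$proximity$p))
  invisible(x)
}

write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE,
                                     fileEncoding = "UTF-8")
  sm <- signal_matrix(x$fit)
  ens <- data.frame(moa = rownames(sm), sm,
                    accuracy = unname(accuracies(x$fit)),
                    seed = vapply(x$fit$ensemble$moas, function(m) m$seed, 0L),
                    check.names = FALSE)
  tsv(ens, "ensemble.tsv")
  tsv(stratification_table(indication = x$groups$indication,
                           adverse_event = x$groups$adverse_event),
      "stratification.tsv")
  tsv(data.frame(group = rownames(x$group_distances), x$group_distances,
                 check.names = FALSE), "group_distances.tsv")
  tsv(data.frame(group = names(x$dispersions),
                 dispersion = unname(x$dispersions)), "dispersion.tsv")
  writeLines(x$dendrogram$newick, file.path(dir, "dendrogram.nwk"))
  tsv(data.frame(moa = rownames(x$mds), x$mds, check.names = FALSE),
      "mds.tsv")
  tsv(x$biomarkers, "biomarkers.tsv")
  writeLines(to_json(list(
    seed = x$seed,
    proximity_overlap = x$proximity$count,
    proximity_p = x$proximity$p,
    overlap = as.list(x$proximity$overlap)
  )), file.path(dir, "proximity.json"))
  invisible(dir)
}
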