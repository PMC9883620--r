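# End-to-end orchestration of the synthetic study: stimuli -> recordings ->
# SBS maps -> cluster inference -> behavior linkage -> directed connectivity
# -> CCA -> mediation, under a single seeded configuration.

#' Pipeline configuration
#'
#' All stage parameters of [run_pipeline()] in one validated, serializable
#' list. Every stochastic stage derives its own seed deterministically from
#' the master \code{seed} via [derive_seed()], so identical configurations
#' give byte-identical numeric results.
#'
#' The defaults define the package's reference synthetic study at desk
#' scale: 48 subjects, 4 stories of 15 s, an 8x8x8 grid with an ellipsoidal
#' mask (~125 voxels), an 18-voxel coupled patch at rho_c = 0.6 in the
#' syllable band, a planted trait-behavior correlation near -0.6, and a
#' five-node directed network with one trait-modulated top-down edge (left
#' premotor to left SBS-ROI) whose phenotype carries most of the behavioral
#' drive, planting a partial mediation.
#'
#' @param n_subjects,n_stories,story_duration_s,fs,grid_dims,mask_radii,rho_c,delay_ms,syllable_rate_hz,jitter_cv,behavior_slope,behavior_noise_sd,family_pair_frac see [simulation_config()].
#' @param n_rand surrogate randomizations.
#' @param alpha cluster-forming threshold.
#' @param n_perm_cluster,n_perm_corr,n_perm_cca permutation counts of the
#'   three permutation tests.
#' @param min_cluster minimum surviving correlation-cluster size.
#' @param n_pc spectral PCs retained per edge.
#' @param gc_order fixed VAR order for edge GC (NULL selects by BIC up to
#'   \code{gc_order_max}).
#' @param gc_order_max BIC scan cap.
#' @param gc_samples samples simulated per subject for the parcel network.
#' @param freqs GC frequency grid in Hz.
#' @param n_boot mediation bootstrap replicates.
#' @param td_base,td_slope,td_noise_sd planted top-down coupling:
#'   per-subject coefficient \code{td_base + td_slope * trait + noise}.
#' @param behavior_td_mix fraction of the behavioral drive contributed by
#'   the top-down coupling phenotype (the rest is the coupling trait), which
#'   plants a partial mediation of the SBS-behavior link.
#' @param stages character vector of enabled stages, in order:
#'   \code{"stimuli", "recordings", "sbs", "cluster", "behavior",
#'   "connectivity", "linkage"}.
#' @param out_dir optional directory; when set, stage outputs are written as
#'   TSV/JSON plus a manifest.
#' @param seed master seed.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subjects = 48, n_stories = 4,
                            story_duration_s = 15, fs = 200,
                            grid_dims = c(8, 8, 8),
                            mask_radii = c(3.1, 3.1, 3.1),
                            rho_c = 0.6, delay_ms = 120,
                            syllable_rate_hz = 4.5, jitter_cv = 0.2,
                            behavior_slope = 12, behavior_noise_sd = 2,
                            family_pair_frac = 0.2,
                            n_rand = 10, alpha = 0.001,
                            n_perm_cluster = 200, n_perm_corr = 500,
                            n_perm_cca = 500, min_cluster = 5, n_pc = 3,
                            gc_order = NULL, gc_order_max = 6,
                            gc_samples = 4000, freqs = 1:100,
                            n_boot = 500, td_base = 0.08, td_slope = 0.35,
                            td_noise_sd = 0.15, behavior_td_mix = 0.7,
                            stages = c("stimuli", "recordings", "sbs",
                                       "cluster", "behavior", "connectivity",
                                       "linkage"),
                            out_dir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  known <- c("stimuli", "recordings", "sbs", "cluster", "behavior",
             "connectivity", "linkage")
  stopifnot(all(stages %in% known), rho_c >= 0, rho_c < 1)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d subjects, %d stories x %gs at %g Hz, seed %d\n",
              x$n_subjects, x$n_stories, x$story_duration_s, x$fs, x$seed))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Save / load a pipeline configuration
#'
#' Plain-text round trip: \code{load_config(save_config(cfg, p))} recreates
#' the configuration exactly.
#'
#' @param config a \code{pipeline_config}.
#' @param path file path.
#' @return \code{save_config} the path; \code{load_config} the configuration.
#' @export
save_config <- function(config, path) {
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- dget(path)
  do.call(pipeline_config, cfg[names(cfg) %in% names(formals(pipeline_config))])
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, compress = FALSE)
  unname(tools::md5sum(f))
}

# five-node directed network with one trait-modulated top-down edge
td_network_nodes <- function() c("PRG_L", "ROI_L", "A1_L", "ROI_R", "PRG_R")

td_network_edges <- function() {
  data.frame(
    source = c("PRG_L", "ROI_L", "PRG_R", "ROI_R", "A1_L", "ROI_L"),
    target = c("ROI_L", "PRG_L", "ROI_R", "PRG_R", "ROI_L", "A1_L"),
    hemisphere = c("L", "L", "R", "R", "L", "L"),
    family = c("TD", "BU", "TD", "BU", "BU", "TD"),
    stringsAsFactors = FALSE)
}

td_network_spec <- function(td_coef, fs) {
  nodes <- td_network_nodes()
  m <- length(nodes)
  A <- array(0, c(m, m, 2), dimnames = list(nodes, nodes, NULL))
  for (i in seq_len(m)) {
    A[i, i, 1] <- 0.5
    A[i, i, 2] <- -0.2
  }
  A["ROI_L", "PRG_L", 1] <- td_coef       # planted, subject-specific
  A["ROI_L", "A1_L", 1] <- 0.10           # fixed bottom-up auditory input
  var_network_spec(A, diag(m), fs = fs)
}

stage_gate <- function(results, need, stage) {
  key <- c(stimuli = "stimuli", recordings = "recording_gen", sbs = "sbs",
           cluster = "cluster_test", behavior = "behavior",
           connectivity = "gc", linkage = "cca")[need]
  if (is.null(results[[key]]))
    stop(sprintf("stage '%s' requires the output of disabled stage '%s'",
                 stage, need))
}

#' Run the synthetic analysis pipeline end-to-end
#'
#' Executes the enabled stages in order on fully synthetic data with planted
#' ground truth: quasi-rhythmic story envelopes with annotations and derived
#' bands; per-subject source recordings whose syllable-band envelope coupling
#' scales with a latent trait; real and surrogate GCMI maps; the family-aware
#' cluster permutation test; behavioral scores transformed, deconfounded and
#' correlated voxelwise with SBS (permutation threshold + cluster pruning);
#' per-subject directed parcel networks with a trait-modulated top-down edge,
#' spectral Granger causality on the registered edges; per-edge CCA against
#' (SBS, WiN') with permutation/FDR; and mediation of the SBS-WiN'
#' relationship by the CCA-weighted top-down connectivity.
#'
#' @param config a [pipeline_config()].
#' @return Object of class \code{sbswin_pipeline}: a list of stage results
#'   (\code{bands}, \code{sbs}, \code{cluster_test}, \code{behavior},
#'   \code{corr_map}, \code{pruned_mask}, \code{gc}, \code{cca},
#'   \code{mediation}, \code{manifest}, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  st <- config$stages
  fs <- config$fs

  if ("stimuli" %in% st) {
    envs <- lapply(seq_len(config$n_stories), function(s)
      gen_envelope(config$syllable_rate_hz, config$jitter_cv,
                   config$story_duration_s, fs,
                   seed = derive_seed(config$seed, paste0("story", s))))
    anns <- lapply(seq_along(envs), function(s)
      gen_annotations(envs[[s]]$events,
                      seed = derive_seed(config$seed, paste0("ann", s)),
                      story_id = paste0("story", s)))
    syl_rates <- vapply(anns, unit_rates, 0, tier = "syllable")
    band <- derive_bands(syl_rates, name = "syllable")
    res$stimuli <- list(envelopes = envs, annotations = anns,
                        syllable_rates = syl_rates)
    res$bands <- list(syllable = band)
  }

  if ("recordings" %in% st) {
    stage_gate(res, "stimuli", "recordings")
    n <- config$n_subjects
    traits <- with_seed(derive_seed(config$seed, "traits"), runif(n))
    simc <- simulation_config(
      n_subjects = n, n_stories = config$n_stories,
      story_duration_s = config$story_duration_s, fs = fs,
      grid_dims = config$grid_dims, mask_radii = config$mask_radii,
      rho_c = config$rho_c, band = res$bands$syllable,
      delay_ms = config$delay_ms,
      syllable_rate_hz = config$syllable_rate_hz,
      jitter_cv = config$jitter_cv, behavior_slope = config$behavior_slope,
      behavior_noise_sd = config$behavior_noise_sd,
      family_pair_frac = config$family_pair_frac, seed = config$seed)
    grid <- config_grid(simc)
    envs <- res$stimuli$envelopes
    # a generator rather than a stored list: one subject's voxel-grid
    # recording lives in memory at a time
    res$recording_gen <- function(i)
      gen_subject_recording(envs, simc, grid, traits[i],
                            seed = derive_seed(config$seed, paste0("rec", i)))
    res$grid <- grid
    res$traits <- traits
    res$coupled_voxels <- default_coupled_patch(grid)
    res$blocks <- make_family_blocks(n, config$family_pair_frac)
  }

  if ("sbs" %in% st) {
    stage_gate(res, "recordings", "sbs")
    sa <- sbs_analysis(res$stimuli$envelopes, res$recording_gen,
                       res$bands$syllable, delay_ms = config$delay_ms,
                       n_rand = config$n_rand,
                       seed = derive_seed(config$seed, "surrogate"),
                       n_subjects = config$n_subjects)
    res$sbs <- sa$real
    res$sbs_surrogate <- sa$surrogate
  }

  if ("cluster" %in% st) {
    stage_gate(res, "sbs", "cluster")
    res$cluster_test <- cluster_perm_test(
      res$sbs, res$sbs_surrogate, res$grid, band = 1, alpha = config$alpha,
      n_perm = config$n_perm_cluster, blocks = res$blocks,
      seed = derive_seed(config$seed, "cluster"))
    res$sig_voxels <- significant_voxels(res$cluster_test)
  }

  if ("behavior" %in% st) {
    stage_gate(res, "cluster", "behavior")
    n <- config$n_subjects
    td <- with_seed(derive_seed(config$seed, "td"), {
      config$td_base + config$td_slope * res$traits +
        rnorm(n, 0, config$td_noise_sd)
    })
    res$td_strength <- td
    td_z <- (td - mean(td)) / sd(td)
    trait_z <- (res$traits - mean(res$traits)) / sd(res$traits)
    drive <- (1 - config$behavior_td_mix) * trait_z + config$behavior_td_mix * td_z
    drive01 <- (drive - min(drive)) / diff(range(drive))
    beh <- gen_behavior(drive01, slope = config$behavior_slope,
                        noise_sd = config$behavior_noise_sd,
                        missing_count = 1,
                        seed = derive_seed(config$seed, "behavior"),
                        family_blocks = res$blocks)
    res$behavior <- beh
    win_prime <- rank_int(beh$threshold_db)
    win_d <- deconfound(win_prime, beh$age)
    res$win_prime <- win_prime
    if (length(res$sig_voxels) == 0) {
      warning("no significant SBS voxels; behavior correlation skipped")
    } else {
      sbs_sig <- res$sbs$values[, res$sig_voxels, 1, drop = TRUE]
      sbs_d <- deconfound(sbs_sig, beh$age)
      cm <- sbs_win_corr_map(sbs_d, win_d, n_perm = config$n_perm_corr,
                             seed = derive_seed(config$seed, "corrperm"))
      res$corr_map <- cm
      full_mask <- logical(nrow(res$grid$coords))
      full_mask[res$sig_voxels[cm$sig]] <- TRUE
      pruned <- prune_clusters(full_mask, res$grid, config$min_cluster)
      res$pruned_mask <- pruned
      res$discard_pct <- discard_rate(attr(pruned, "n_removed_voxels"),
                                      length(res$sig_voxels))
      roi <- which(pruned)
      if (length(roi) > 0) {
        cols <- match(roi, res$sig_voxels)
        res$roi_voxels <- roi
        res$sbs_roi <- rowMeans(sbs_d[, cols, drop = FALSE])
        res$win_d <- win_d
      }
    }
  }

  if ("connectivity" %in% st) {
    stage_gate(res, "behavior", "connectivity")
    n <- config$n_subjects
    series <- lapply(seq_len(n), function(i) {
      spec <- td_network_spec(res$td_strength[i], fs)
      Z <- gen_var_parcels(spec, config$gc_samples,
                           seed = derive_seed(config$seed, paste0("var", i)))
      colnames(Z) <- td_network_nodes()
      Z
    })
    edges <- td_network_edges()
    res$edges <- edges
    res$gc <- edge_gc(series, edges, fs, config$freqs,
                      order_max = config$gc_order_max, order = config$gc_order)
  }

  if ("linkage" %in% st && is.null(res$sbs_roi)) {
    warning("no surviving SBS-behavior ROI; linkage stage skipped")
    st <- setdiff(st, "linkage")
  }
  if ("linkage" %in% st) {
    stage_gate(res, "connectivity", "linkage")
    red <- reduce_spectra(res$gc, n_pc = config$n_pc)
    Y <- cbind(sbs = as.numeric(scale(res$sbs_roi)),
               win = as.numeric(scale(res$win_d)))
    res$cca <- cca_perm_fdr(red$features, Y, n_perm = config$n_perm_cca,
                            seed = derive_seed(config$seed, "cca"))
    res$spectra_reduction <- red
    td_idx <- which(res$edges$family == "TD" & res$edges$hemisphere == "L" &
                      res$edges$source == "PRG_L")
    fit <- attr(res$cca, "fits")[[td_idx]]
    mediator <- as.numeric(scale(red$features[[td_idx]]) %*% fit$xweights[, 1])
    res$mediator <- mediator
    res$mediation <- mediate(res$sbs_roi, mediator, res$win_d,
                             n_boot = config$n_boot,
                             seed = derive_seed(config$seed, "boot"))
    res$td_edge <- td_idx
  }

  res$manifest <- list(config_hash = config_hash(config), seed = config$seed,
                       stages = st, timestamp_free = TRUE,
                       package_version = as.character(utils::packageVersion("sbswin")))
  out <- structure(res, class = "sbswin_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @export
print.sbswin_pipeline <- function(x, ...) {
  cat("<sbswin_pipeline>\n")
  cat(sprintf("  config hash %s, master seed %d\n",
              x$manifest$config_hash, x$config$seed))
  if (!is.null(x$cluster_test)) {
    cl <- x$cluster_test$clusters
    if (nrow(cl) > 0)
      cat(sprintf("  SBS: rank-1 cluster t_sum = %.1f (%d voxels, p = %.3f)\n",
                  cl$t_sum[1], cl$n_voxels[1], cl$p[1]))
    else cat("  SBS: no suprathreshold clusters\n")
  }
  if (!is.null(x$corr_map))
    cat(sprintf("  SBS-WiN: %d/%d voxels significant, %d in surviving clusters (%.2f%% discarded)\n",
                sum(x$corr_map$sig), length(x$corr_map$rho),
                sum(x$pruned_mask), x$discard_pct))
  if (!is.null(x$cca)) {
    td <- x$td_edge
    cat(sprintf("  CCA (planted TD edge %s): rho = %.3f, p_fdr = %.3f\n",
                x$cca$test[td], x$cca$rho[td], x$cca$p_fdr[td]))
  }
  if (!is.null(x$mediation))
    cat(sprintf("  mediation: a*b = %.3f, bootstrap CI [%.3f, %.3f]\n",
                x$mediation$indirect_product, x$mediation$boot_ci[1],
                x$mediation$boot_ci[2]))
  invisible(x)
}

write_pipeline_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(x$cluster_test))
    write.table(as.data.frame(x$cluster_test$clusters),
                file.path(dir, "clusters.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  if (!is.null(x$corr_map)) {
    cm <- data.frame(voxel = x$sig_voxels, rho = x$corr_map$rho,
                     p = x$corr_map$p, significant = x$corr_map$sig)
    write.table(cm, file.path(dir, "sbs_win_correlations.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(x$behavior))
    write.table(as.data.frame(x$behavior), file.path(dir, "behavior.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(x$cca))
    write.table(x$cca, file.path(dir, "cca.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  man <- x$manifest
  writeLines(c(sprintf("config_hash: %s", man$config_hash),
               sprintf("seed: %d", man$seed),
               sprintf("stages: %s", paste(man$stages, collapse = ",")),
               sprintf("package_version: %s", man$package_version)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
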