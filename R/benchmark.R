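#' Scaled-down synthetic detection benchmark
#'
#' Runs the complete study on a synthetic stack at CPU scale: generates
#' `n_sections` dark-field sections (a fraction labeled, the rest treated
#' as unlabeled), trains the reduced dual-head model with supervised
#' pretraining followed by temporal ensembling, segments the held-out
#' sections, applies the continuity and morphology false-positive filters,
#' and evaluates region-level detection (TPR, FPavg, delta-FD, FROC) plus
#' pathway-level fiber densities with a one-way ANOVA.
#'
#' Defaults mirror the synthetic study conditions: 20 sections of
#' 512 x 512 px at 20 µm/px spaced 1.2 mm, 5 labeled + 15 held-out
#' unlabeled, a base-width-4 depth-3 model, 10 pretraining + 5
#' temporal-ensembling epochs, and the operating threshold 0.4.
#'
#' @param seed Integer seed fixing the generator, initialization, and all
#'   sampling.
#' @param n_sections Total sections in the stack.
#' @param n_labeled Number of labeled training sections (the first ones).
#' @param image_px Section side in pixels.
#' @param base_width,depth Reduced model size.
#' @param pretrain_epochs,te_epochs Training epochs per phase.
#' @param patches_per_section Anchor patches per labeled section per epoch.
#' @param threshold Operating probability threshold.
#' @param froc_thresholds Thresholds swept for the FROC curve.
#' @param lr Adam learning rate for the reduced model.
#' @param verbose Emit progress messages.
#' @return List with elements `tpr_raw`, `fpavg_raw`, `tpr_post`,
#'   `fpavg_post`, `delta_fd_pct`, `froc` (data frame with `elbow`
#'   attribute), `fd` (per-bundle density table, section scope),
#'   `fd_manual`, `anova` (list with `F`, `p`, `groups`), `model`,
#'   `train_logs`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_sections = 20L, n_labeled = 5L,
                                image_px = 512L, base_width = 4L, depth = 3L,
                                pretrain_epochs = 10L, te_epochs = 5L,
                                patches_per_section = 8L, threshold = 0.4,
                                froc_thresholds = c(0.8, 0.6, 0.5, 0.4, 0.3, 0.2),
                                lr = 5e-3, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  scfg <- synth_config(image_height_px = image_px, image_width_px = image_px,
                       n_sections = n_sections, seed = seed)
  labeled_idx <- seq_len(n_labeled) - 1L
  say("generating %d synthetic sections (%d labeled)", n_sections, n_labeled)
  stack <- generate_stack(scfg, labeled_sections = labeled_idx)
  as_sample <- function(s) list(section = s$section,
                                annotations = s$annotations,
                                white_matter_mask = NULL,
                                tissue_mask = s$tissue_mask)
  labeled <- lapply(stack[seq_len(n_labeled)], as_sample)
  heldout <- stack[(n_labeled + 1):n_sections]
  unlabeled <- lapply(heldout, as_sample)

  model <- build_model(model_config(base_width = base_width, depth = depth,
                                    fc_sizes = c(64L, 32L)),
                       seed = derive_seed(seed, 2L))
  tcfg <- train_config(lr = lr, pretrain_epochs = pretrain_epochs,
                       te_epochs = te_epochs,
                       patches_per_section = patches_per_section,
                       batch_size = 8L,
                       loss_weights = list(focal = 1, contrastive = 0.05),
                       seed = derive_seed(seed, 3L))
  say("pretraining %d epochs on %d labeled sections", pretrain_epochs, n_labeled)
  pt <- pretrain(model, labeled, tcfg)
  model <- pt$model
  logs <- pt$logs
  if (te_epochs > 0) {
    say("temporal ensembling for %d epochs over %d unlabeled sections",
        te_epochs, length(unlabeled))
    te <- train_te(model, labeled, unlabeled, tcfg)
    model <- te$model
    common <- intersect(names(logs), names(te$logs))
    logs <- rbind(logs[, common], te$logs[, common])
  }

  sections <- lapply(heldout, `[[`, "section")
  tissue <- lapply(heldout, `[[`, "tissue_mask")
  manual <- lapply(heldout, `[[`, "truth")
  rois <- lapply(heldout, `[[`, "pathway_rois")
  say("segmenting %d held-out sections", length(sections))
  pmaps <- lapply(sections, function(s) predict_section(model, s))

  raw <- lapply(seq_along(sections), function(i) {
    regions_from_mask(binarize(pmaps[[i]], threshold),
                      sections[[i]]$um_per_px,
                      sections[[i]]$section_index, tissue[[i]])
  })
  post <- postprocess_stack(sections, pmaps, tissue, threshold = threshold)
  m_raw <- lapply(seq_along(sections), function(i)
    match_bundles(manual[[i]], raw[[i]]))
  m_post <- lapply(seq_along(sections), function(i)
    match_bundles(manual[[i]], post[[i]]))

  fdp <- clahe_params(scope = "section")
  ev <- evaluate_detection(sections, manual, post, fd_params = fdp,
                           tissue_masks = tissue)
  say("sweeping FROC thresholds")
  curve <- froc(sections, pmaps, manual, tissue,
                thresholds = froc_thresholds)
  fd_pred <- fd_table(sections, post, rois, fdp, tissue)
  fd_man <- fd_table(sections, manual, rois, fdp, tissue)
  an <- tryCatch(pathway_anova(fd_pred), error = function(e) NULL)

  list(tpr_raw = tpr_pooled(m_raw), fpavg_raw = fp_avg(m_raw),
       tpr_post = tpr_pooled(m_post), fpavg_post = fp_avg(m_post),
       delta_fd_pct = ev$delta_fd_pct,
       froc = curve, fd = fd_pred, fd_manual = fd_man, anova = an,
       model = model, train_logs = logs)
}
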