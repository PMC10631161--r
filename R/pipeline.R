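# Gluing the stages together: preprocessing phantom cases into training
# pairs, whole-cohort evaluation, and the ablation harness that retrains
# configuration variants under one shared seed and split.

#' Preprocess a case into a training pair
#'
#' Applies the full image chain (window, resample, normalize) to the image
#' and the companion chain (nearest-neighbour resample only) to the mask.
#'
#' @param case A `phantom_case` or list with `image` ([ct_volume()], HU)
#'   and `mask` ([ct_mask()]).
#' @param level,width,inplane_factor,target_z_spacing See [preprocess()].
#' @return List with preprocessed `image` and `mask`.
#' @export
preprocess_case <- function(case, level = 40, width = 300,
                            inplane_factor = 0.5, target_z_spacing = 1.0) {
  list(image = preprocess(case$image, level, width, inplane_factor, target_z_spacing),
       mask = preprocess(case$mask, level, width, inplane_factor, target_z_spacing))
}

#' Predict and evaluate a set of cases
#'
#' Runs slab-wise whole-volume prediction, binarizes at the threshold, and
#' evaluates the five metrics against ground truth.
#'
#' @param model A trained `dst_net`.
#' @param cases Preprocessed case pairs (as from [preprocess_case()]).
#' @param slab_depth,overlap See [predict_volume()].
#' @param threshold See [binarize()].
#' @param units Distance units for surface metrics.
#' @return As [evaluate_cases()]: `per_case` and `mean`.
#' @export
evaluate_model <- function(model, cases, slab_depth = 32L, overlap = 0L,
                           threshold = 0.5, units = "mm") {
  preds <- lapply(cases, function(cs) {
    binarize(predict_volume(model, cs$image, slab_depth, overlap), threshold)
  })
  truths <- lapply(cases, function(cs) cs$mask)
  evaluate_cases(preds, truths, units = units)
}

#' Component and depth ablation grids
#'
#' `ablation_component_grid()` reproduces the three-row major-component
#' design (encoder-decoder backbone alone; + skip connections; + skip
#' connections and transformer). `ablation_depth_grid()` varies the
#' transformer depth over 2/4/6/8 layers with all components active.
#'
#' @param layers Depths for the depth grid.
#' @return Data frame with columns `ed`, `sc`, `tf`, `layers`.
#' @export
ablation_component_grid <- function() {
  data.frame(ed = TRUE, sc = c(FALSE, TRUE, TRUE), tf = c(FALSE, FALSE, TRUE),
             layers = 4L)
}

#' @rdname ablation_component_grid
#' @export
ablation_depth_grid <- function(layers = c(2L, 4L, 6L, 8L)) {
  data.frame(ed = TRUE, sc = TRUE, tf = TRUE, layers = as.integer(layers))
}

#' Run an ablation experiment
#'
#' Trains one model per grid row - identical data, training configuration,
#' seed and case split throughout - and evaluates each on the shared test
#' split. The encoder-decoder backbone (`ed`) is the architecture itself
#' and cannot be ablated; the transformer requires it.
#'
#' @param cases Preprocessed case pairs.
#' @param base_config A [net_config()] template (its `use_skip`,
#'   `use_transformer`, `n_transformer_layers` are overridden per row).
#' @param tcfg A [train_config()].
#' @param grid Data frame with columns `ed`, `sc`, `tf`, `layers` (see
#'   [ablation_component_grid()]).
#' @param units Distance units for surface metrics.
#' @return Data frame: one row per variant with the flags, parameter count
#'   and the five mean test metrics.
#' @export
run_ablation <- function(cases, base_config, tcfg, grid = ablation_component_grid(),
                         units = "mm") {
  stopifnot(inherits(base_config, "net_config"), inherits(tcfg, "train_config"))
  need <- c("ed", "sc", "tf", "layers")
  if (!all(need %in% names(grid))) stop("grid must have columns ", paste(need, collapse = ", "))
  if (any(!grid$ed)) stop("the encoder-decoder backbone (ED) cannot be ablated")
  split <- split_cases(cases, tcfg$train_fraction, tcfg$seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    cfg <- net_config(input_size = base_config$input_size,
                      in_channels = base_config$in_channels,
                      stem_channels = base_config$stem_channels,
                      n_transformer_layers = if (row$tf) row$layers else 0L,
                      n_heads = base_config$n_heads,
                      use_skip = row$sc, use_transformer = row$tf,
                      ffn_ratio = base_config$ffn_ratio,
                      dropout = base_config$dropout)
    model <- init_network(cfg, tcfg$seed)
    fit <- train(model, split$train, tcfg)
    ev <- evaluate_model(fit$model, split$test, tcfg$slab_depth, units = units)
    data.frame(ed = TRUE, sc = row$sc, tf = row$tf,
               layers = if (row$tf) row$layers else 0L,
               n_parameters = n_parameters(fit$model),
               dsc = ev$mean[["dsc"]], hausdorff = ev$mean[["hausdorff"]],
               iou = ev$mean[["iou"]], mae = ev$mean[["mae"]],
               asd = ev$mean[["asd"]])
  })
  do.call(rbind, rows)
}
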