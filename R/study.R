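#' Run one stepwise verification study end to end
#'
#' Generates a dataset for the requested family, splits it 64/16/20,
#' flip-augments train and validation, trains the dose estimator and
#' evaluates it on the held-out test split. This is the package's
#' one-call reproduction of a study family; all randomness flows from
#' the R seed in effect when it is called.
#'
#' @param family `"A"`, `"B"` or `"C"`.
#' @param n_samples Dataset size.
#' @param n_protons Primaries per sample.
#' @param with_ct Condition the model on the density grid (family C).
#' @param model_cfg A `model_config` (`NULL`: family default).
#' @param transport_cfg A `transport_config`.
#' @param criteria Gamma criteria for the evaluation.
#' @param overrides Generator overrides, see [generate_dataset()].
#' @param keep_dataset Return the dataset (memory permitting).
#' @param progress Print generation/training progress.
#' @return List: `report` (`eval_report`), `model`, `split`, and
#'   optionally `dataset`.
#' @export
run_study <- function(family, n_samples = 200, n_protons = 5e4,
                      with_ct = FALSE, model_cfg = NULL,
                      transport_cfg = transport_config(),
                      criteria = gamma_criteria(),
                      overrides = list(), keep_dataset = FALSE,
                      progress = FALSE) {
  if (is.null(model_cfg))
    model_cfg <- switch(family,
                        A = model_config(encoder_hidden = 64,
                                         latent = 32,
                                         decoder_hidden = 256,
                                         lr = 1e-3, epochs = 120),
                        B = model_config(encoder_hidden = 64,
                                         latent = 48,
                                         decoder_hidden = 256,
                                         lr = 1e-3, epochs = 55,
                                         input_noise_sd = 0.02),
                        C = model_config(encoder_hidden = 64,
                                         latent = 32, ct_latent = 32,
                                         decoder_hidden = 96,
                                         lr = 1e-3, epochs = 35,
                                         input_noise_sd = 0.01,
                                         val_every = 5L))
  ds <- generate_dataset(family, n_samples, n_protons,
                         cfg = transport_cfg, overrides = overrides,
                         progress = progress)
  sp <- split_dataset(ds)
  tr <- augment_flips(ds, sp$train)
  va <- augment_flips(ds, sp$val)
  s1 <- ds$samples[[1]]
  model <- build_model(model_cfg, length(s1$currents),
                       length(s1$target), dim(s1$target),
                       with_ct = with_ct,
                       ct_dim = if (with_ct)
                         length(pool_grid(s1$ct, model_cfg$ct_pool)))
  model <- train_model(model, tr, va, quiet = !progress)
  report <- evaluate_testset(model, ds, sp$test, criteria)
  out <- list(report = report, model = model, split = sp)
  if (keep_dataset) out$dataset <- ds
  out
}
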