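#' Configuration for the digital multi-compound phantom experiment
#'
#' Bundles every knob of the end-to-end study: the dictionary grids, the
#' training schedule, the phantom noise level and the seeds. Three presets
#' trade accuracy for runtime:
#' \describe{
#'   \item{full}{the shipped default grids (29,400 / 46,080 / 84,672
#'     dictionary rows for the MT, rNOE and amide/glutamate stages) with
#'     noise-replicate oversampling of the smaller dictionaries;}
#'   \item{reduced}{grids thinned by a factor 2 per dimension;}
#'   \item{tiny}{aggressively thinned grids for smoke tests.}
#' }
#'
#' @param scale `"full"`, `"reduced"`, or `"tiny"`.
#' @param seed Master seed; the phantom noise and each network's training
#'   stream derive from it.
#' @param noise_sigma Gaussian noise level as a fraction of M0, applied
#'   both to the phantom and as training augmentation.
#' @param spec Phantom specification (defaults to [phantom_spec()]).
#' @return An object of class `cest_fig2_config`.
#' @export
fig2_config <- function(scale = c("full", "reduced", "tiny"), seed = 0,
                        noise_sigma = 0.01, spec = phantom_spec()) {
  scale <- match.arg(scale)
  grids <- list(mt = default_grid("mt"), rnoe = default_grid("rnoe"),
                amideglu = default_grid("amideglu"))
  thin_by <- switch(scale, full = 1, reduced = 2, tiny = 3)
  if (thin_by > 1) grids <- lapply(grids, thin_grid, by = thin_by)
  copies <- switch(scale,
                   full = c(mt = 4, rnoe = 3, amideglu = 1),
                   reduced = c(mt = 10, rnoe = 6, amideglu = 4),
                   tiny = c(mt = 10, rnoe = 8, amideglu = 6))
  epochs <- switch(scale,
                   full = c(mt = 30, rnoe = 30, amideglu = 50),
                   reduced = c(mt = 25, rnoe = 25, amideglu = 40),
                   tiny = c(mt = 12, rnoe = 12, amideglu = 15))
  # clean warm-up epochs before noise augmentation starts (see
  # training_config(noiseless_epochs=))
  warmup <- switch(scale,
                   full = c(mt = 5, rnoe = 5, amideglu = 12),
                   reduced = c(mt = 4, rnoe = 4, amideglu = 10),
                   tiny = c(mt = 2, rnoe = 2, amideglu = 5))
  structure(list(scale = scale, seed = seed, noise_sigma = noise_sigma,
                 spec = spec, grids = grids, copies = copies,
                 epochs = epochs, warmup = warmup, patience = 6),
            class = "cest_fig2_config")
}

#' Run the digital multi-compound phantom experiment end to end
#'
#' Chains the whole workflow: build the four MRF protocol schedules,
#' simulate the per-stage dictionaries, train the three quantification
#' networks, synthesize the noisy 5 x 5 x 4-background phantom, quantify
#' it pixelwise, and evaluate vial-mean parameter recovery. Deterministic
#' given the configuration.
#'
#' @param config A [fig2_config()].
#' @param verbose Print stage timings.
#' @return List with `report` (a `cest_recovery_report`), `targets` (named
#'   summary statistics, see [fig2_targets()]), `quant`, `phantom`,
#'   `models`, `config`, `config_hash` and per-stage `timings` (seconds).
#' @export
run_fig2_experiment <- function(config = fig2_config(), verbose = FALSE) {
  stopifnot(inherits(config, "cest_fig2_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  schedules <- lapply(stats::setNames(nm = c("mt", "rnoe", "amide", "glu")),
                      default_schedule)
  t0 <- tic()
  base <- function(g) .grid_base_tissue(g, config$spec$base_tissue)
  dicts <- list(
    mt = generate_dictionary(config$grids$mt, schedules$mt,
                             base(config$grids$mt)),
    rnoe = generate_dictionary(config$grids$rnoe, schedules$rnoe,
                               base(config$grids$rnoe)),
    amideglu = generate_dictionary(config$grids$amideglu,
                                   list(schedules$amide, schedules$glu),
                                   base(config$grids$amideglu)))
  timings["dictionaries"] <- tic() - t0
  say("dictionaries: %.1f s (%d + %d + %d rows)", timings["dictionaries"],
      nrow(dicts$mt$params), nrow(dicts$rnoe$params),
      nrow(dicts$amideglu$params))
  models <- list()
  for (i in seq_along(nets <- c("mt", "rnoe", "amideglu"))) {
    nm <- nets[i]
    t0 <- tic()
    models[[nm]] <- train_cest_net(
      dicts[[nm]], nm,
      training_config(epochs = config$epochs[[nm]],
                      patience = config$patience,
                      noise_sigma = config$noise_sigma,
                      noise_copies = config$copies[[nm]],
                      noiseless_epochs = config$warmup[[nm]],
                      seed = config$seed + 101 * i))
    timings[paste0("train_", nm)] <- tic() - t0
    say("train %s: %.1f s (best val MSE %.2e, epoch %d)", nm,
        timings[paste0("train_", nm)], models[[nm]]$val_loss,
        models[[nm]]$best_epoch)
  }
  t0 <- tic()
  phantom <- make_digital_phantom(config$spec, schedules,
                                  noise_sigma = config$noise_sigma,
                                  seed = config$seed)
  quant <- run_pipeline(phantom, models)
  report <- phantom_recovery_report(quant, phantom)
  timings["phantom_quantify"] <- tic() - t0
  say("phantom + quantify + stats: %.1f s", timings["phantom_quantify"])
  list(report = report, targets = fig2_targets(report), quant = quant,
       phantom = phantom, models = models, config = config,
       config_hash = config_hash(list(
         scale = config$scale, seed = config$seed,
         noise_sigma = config$noise_sigma,
         grids = lapply(config$grids, `[[`, "values"))),
       timings = timings)
}

#' Summary statistics of the phantom experiment
#'
#' Extracts the six headline recovery statistics: Pearson r and ICC for
#' the semisolid MT volume fraction over all vials, and the minimum
#' per-background Pearson r and ICC for the amide volume fraction and the
#' glutamate concentration.
#'
#' @param report A `cest_recovery_report`.
#' @return Named numeric vector: `mt_fss_r`, `mt_fss_icc`,
#'   `amide_min_r`, `amide_min_icc`, `glu_min_r`, `glu_min_icc`.
#' @export
fig2_targets <- function(report) {
  tab <- report$table
  pb <- report$per_background
  pick <- function(p, col) tab[tab$parameter == p, col]
  pick_bg <- function(p, col) min(pb[pb$parameter == p, col])
  c(mt_fss_r = pick("f_ss", "r"), mt_fss_icc = pick("f_ss", "icc"),
    amide_min_r = pick_bg("f_amide", "r"),
    amide_min_icc = pick_bg("f_amide", "icc"),
    glu_min_r = pick_bg("glu_mM", "r"),
    glu_min_icc = pick_bg("glu_mM", "icc"))
}
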