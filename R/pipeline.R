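#' Run the sequential three-network quantification pipeline
#'
#' Applies the trained networks pixelwise: the semisolid MT network first
#' (normalized MT-protocol trajectory + water T1/T2), whose `f_ss`/`k_ssw`
#' estimates are then shared with the rNOE network and the combined
#' amide/glutamate network together with their protocol trajectories. The
#' result is the set of eight parameter maps. Pixels outside the mask are
#' zero.
#'
#' @param phantom A [make_digital_phantom()] dataset (or any object with
#'   the same `traj`/`t1_map`/`t2_map`/`vial_id` layout).
#' @param models Named list with trained `mt`, `rnoe` and `amideglu`
#'   [train_cest_net()] models.
#' @param mask Optional logical matrix; defaults to the phantom's non-
#'   background pixels.
#' @param check_hash Refuse inference when a model's training schedule hash
#'   does not match the data's acquisition schedule hash (default `TRUE`).
#' @return An object of class `cest_quantmaps`: `maps` is a named list of
#'   eight arrays (image x image x backgrounds) — `f_ss`, `k_ssw`,
#'   `f_rnoe`, `k_rnoe`, `f_amide`, `k_amide` (volume fractions
#'   dimensionless, rates in 1/s), `glu_mM` (mM) and `k_glu` (1/s).
#' @export
run_pipeline <- function(phantom, models, mask = NULL, check_hash = TRUE) {
  stopifnot(all(c("mt", "rnoe", "amideglu") %in% names(models)))
  for (m in models[c("mt", "rnoe", "amideglu")])
    stopifnot(inherits(m, "cest_net"))
  traj <- phantom$traj
  need <- c("mt", "rnoe", "amide", "glu")
  if (!all(need %in% names(traj)))
    stop("phantom must carry trajectory stacks named ",
         paste(need, collapse = ", "))
  d <- dim(traj$mt)
  if (length(d) != 4) stop("trajectory stacks must be 4-D arrays")
  for (pn in need)
    if (!identical(dim(traj[[pn]]), d))
      stop("trajectory stack shapes differ across protocols")
  if (!identical(dim(phantom$t1_map), d[1:2]))
    stop("T1/T2 map shape does not match the trajectory stacks")
  if (check_hash && !is.null(phantom$schedule_hash)) {
    ph <- phantom$schedule_hash
    ok <- identical(unname(models$mt$schedule_hash), unname(ph[["mt"]])) &&
      identical(unname(models$rnoe$schedule_hash), unname(ph[["rnoe"]])) &&
      identical(unname(models$amideglu$schedule_hash),
                unname(ph[c("amide", "glu")]))
    if (!ok)
      stop("model/schedule hash mismatch: the models were trained on a ",
           "different acquisition schedule (set check_hash = FALSE to ",
           "override)")
  }
  n1 <- d[1]; n2 <- d[2]; ne <- d[3]; nb <- d[4]
  if (is.null(mask)) {
    mask <- if (!is.null(phantom$vial_id)) phantom$vial_id > 0
            else matrix(TRUE, n1, n2)
  }
  out_names <- c("f_ss", "k_ssw", "f_rnoe", "k_rnoe", "f_amide", "k_amide",
                 "glu_mM", "k_glu")
  maps <- lapply(stats::setNames(nm = out_names),
                 function(x) array(0, c(n1, n2, nb)))
  pix <- which(mask)
  if (length(pix)) {
    for (ib in seq_len(nb)) {
      get_mat <- function(pn)
        matrix(traj[[pn]][, , , ib], n1 * n2, ne)[pix, , drop = FALSE]
      scalars <- cbind(water_t1 = phantom$t1_map[pix],
                       water_t2 = phantom$t2_map[pix])
      mt_est <- predict(models$mt, get_mat("mt"), scalars)
      scalars2 <- cbind(scalars, mt_est)
      rnoe_est <- predict(models$rnoe, get_mat("rnoe"), scalars2)
      ag_est <- predict(models$amideglu,
                        list(get_mat("amide"), get_mat("glu")), scalars2)
      est <- cbind(mt_est, rnoe_est, ag_est)
      for (nm in out_names) {
        plane <- matrix(0, n1, n2)
        plane[pix] <- est[, nm]
        maps[[nm]][, , ib] <- plane
      }
    }
  }
  structure(list(maps = maps, mask = mask,
                 schedule_hash = list(
                   mt = models$mt$schedule_hash,
                   rnoe = models$rnoe$schedule_hash,
                   amideglu = models$amideglu$schedule_hash)),
            class = "cest_quantmaps")
}

#' @export
print.cest_quantmaps <- function(x, ...) {
  d <- dim(x$maps$f_ss)
  cat(sprintf("<cest_quantmaps> 8 maps, %dx%d px x %d background(s), %d masked pixels\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Evaluate parameter recovery against phantom ground truth
#'
#' Convenience wrapper around [phantom_recovery_report()]: computes vial
#' means over the truth-vial masks and the per-parameter Pearson, ICC,
#' bias and RMSE statistics.
#'
#' @inheritParams phantom_recovery_report
#' @return A `cest_recovery_report`.
#' @export
evaluate_recovery <- function(quant, truth) {
  phantom_recovery_report(quant, truth)
}

#' Plot recovery scatter panels
#'
#' One panel per varied parameter (semisolid MT, glutamate, amide):
#' estimated vs true vial means with the identity line.
#'
#' @param x A `cest_recovery_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cest_recovery_report <- function(x, ...) {
  vt <- x$vials
  panels <- list(
    c("truth_f_ss", "est_f_ss", "semisolid MT f_ss"),
    c("truth_glu_mM", "est_glu_mM", "glutamate [mM]"),
    c("truth_f_amide", "est_f_amide", "amide f_s"))
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (p in panels) {
    graphics::plot(vt[[p[1]]], vt[[p[2]]], xlab = "truth",
                   ylab = "estimate", main = p[3], ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
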