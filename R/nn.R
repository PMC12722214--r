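#' Specify a quantification network
#'
#' Fully connected architecture used by the sequential pipeline: rectified
#' (ReLU) hidden layers of 300 neurons each and a sigmoid output layer whose
#' units are mapped to physical parameter ranges by a per-parameter
#' min-max affine scaling. The semisolid MT and rNOE networks use two
#' hidden layers; the combined amide/glutamate network uses four (it solves
#' the harder joint problem of two spectrally adjacent pools).
#'
#' @param name Network label.
#' @param input_size Number of input neurons.
#' @param output_names Ordered parameter labels produced by the network.
#' @param output_scaling 2 x p matrix (rows `min`, `max`) mapping the
#'   sigmoid range to physical units per output.
#' @param hidden Hidden-layer widths (default two layers of 300).
#' @return An object of class `cest_net_spec`.
#' @export
network_spec <- function(name, input_size, output_names, output_scaling,
                         hidden = c(300, 300)) {
  output_scaling <- as.matrix(output_scaling)
  stopifnot(nrow(output_scaling) == 2, ncol(output_scaling) ==
              length(output_names), all(hidden >= 1), input_size >= 1)
  if (any(output_scaling[2, ] <= output_scaling[1, ]))
    stop("output scaling must have max > min for every parameter")
  rownames(output_scaling) <- c("min", "max")
  colnames(output_scaling) <- output_names
  structure(list(name = name, input_size = input_size, hidden = hidden,
                 hidden_activation = "relu", output_activation = "sigmoid",
                 output_names = output_names,
                 output_scaling = output_scaling),
            class = "cest_net_spec")
}

# Outputs regressed by each pipeline network.
.net_outputs <- function(network) {
  switch(network,
         mt = c("f_ss", "k_ssw"),
         rnoe = c("f_rnoe", "k_rnoe"),
         amideglu = c("f_amide", "k_amide", "glu_mM", "k_glu"),
         stop("unknown network '", network, "'"))
}

# Upstream parameters fed forward from the MT stage.
.net_upstream <- function(network) {
  if (network %in% c("rnoe", "amideglu")) c("f_ss", "k_ssw") else character(0)
}

#' Default network specification for a pipeline stage
#'
#' Input sizes follow the pipeline wiring: 30 normalized trajectory entries
#' plus water T1 and T2 for the MT network (32); plus the upstream
#' `f_ss`/`k_ssw` estimates for the rNOE network (34); and two 30-entry
#' trajectories plus the four scalars for the combined amide/glutamate
#' network (64). Output scaling ranges are the min/max of the training
#' grid.
#'
#' @param network `"mt"`, `"rnoe"` or `"amideglu"`.
#' @param grid The training [parameter_grid()] (defaults to
#'   [default_grid()] for the stage).
#' @param n_entries Trajectory entries per protocol including M0.
#' @return A [network_spec()].
#' @export
default_network_spec <- function(network = c("mt", "rnoe", "amideglu"),
                                 grid = NULL, n_entries = 31) {
  network <- match.arg(network)
  if (is.null(grid)) grid <- default_grid(network)
  outs <- .net_outputs(network)
  missing <- setdiff(outs, names(grid$values))
  if (length(missing))
    stop("grid lacks parameters required by the ", network, " network: ",
         paste(missing, collapse = ", "))
  scaling <- vapply(outs, function(nm) range(grid$values[[nm]]), numeric(2))
  n_traj <- (n_entries - 1) * if (network == "amideglu") 2 else 1
  n_scalar <- 2 + length(.net_upstream(network))
  network_spec(name = network, input_size = n_traj + n_scalar,
               output_names = outs, output_scaling = scaling,
               hidden = rep(300, if (network == "amideglu") 4 else 2))
}

#' Training configuration
#'
#' Defaults follow the quantification pipeline's reference hyperparameters:
#' Adam with learning rate 0.0002, minibatch 1024, and mean squared error
#' on min-max-scaled targets. White Gaussian noise (standard deviation
#' `noise_sigma` of M0) is injected into the raw trajectories before
#' normalization, re-drawn every epoch, to promote robustness; small
#' dictionaries can be oversampled with `noise_copies` independent noisy
#' replicates. Early stopping monitors validation MSE.
#'
#' @param learning_rate Adam learning rate.
#' @param minibatch Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs.
#' @param validation_fraction Fraction of dictionary rows held out.
#' @param noise_sigma Training noise level as a fraction of M0.
#' @param noise_copies Noisy replicates of each dictionary row per epoch.
#' @param noiseless_epochs Number of initial epochs trained without noise
#'   injection. The clean warm-up lets the network fit the deterministic
#'   inverse map (in particular the semisolid-background correction of the
#'   dilute-pool outputs) with low-variance gradients before the noisy
#'   phase instills robustness; early stopping only starts once noise is
#'   on.
#' @param seed Integer seed; training is bit-reproducible given the seed.
#' @return An object of class `cest_train_config`.
#' @export
training_config <- function(learning_rate = 2e-4, minibatch = 1024,
                            epochs = 200, patience = 10,
                            validation_fraction = 0.2, noise_sigma = 0.01,
                            noise_copies = 1, noiseless_epochs = 0,
                            seed = 1) {
  stopifnot(learning_rate > 0, minibatch >= 1, epochs >= 1, patience >= 1,
            validation_fraction >= 0, validation_fraction < 1,
            noise_sigma >= 0, noise_copies >= 1, noiseless_epochs >= 0)
  structure(list(learning_rate = learning_rate, minibatch = minibatch,
                 epochs = epochs, patience = patience,
                 validation_fraction = validation_fraction,
                 noise_sigma = noise_sigma, noise_copies = noise_copies,
                 noiseless_epochs = noiseless_epochs, seed = seed),
            class = "cest_train_config")
}

# Raw trajectory matrices of a dictionary as a list (one per protocol).
.dict_traj_list <- function(dictionary) {
  if (is.list(dictionary$traj)) dictionary$traj else list(dictionary$traj)
}

# Scalar input columns for a stage: water T1, T2, then upstream parameters.
.scalar_cols <- function(network) c("water_t1", "water_t2",
                                    .net_upstream(network))

#' Build a training set from a dictionary
#'
#' Assembles network inputs (noise-injected, M0-referenced, L2-normalized
#' trajectories concatenated with the scalar inputs) and min-max-scaled
#' targets for one pipeline stage. Downstream stages are trained with the
#' true upstream parameters from the grid (at inference they receive the
#' MT-stage estimates).
#'
#' @param dictionary A [generate_dictionary()] result.
#' @param network `"mt"`, `"rnoe"` or `"amideglu"`.
#' @param spec Optional [network_spec()]; defaults to the stage default
#'   built from the dictionary's grid.
#' @param noise_sigma Noise fraction of M0 injected before normalization.
#' @param seed Integer seed for the noise draw.
#' @return List with `inputs`, `targets` (scaled to (0, 1)),
#'   `scalar_scaling`, and `spec`.
#' @export
build_training_set <- function(dictionary, network = c("mt", "rnoe",
                                                       "amideglu"),
                               spec = NULL, noise_sigma = 0.01, seed = 1) {
  network <- match.arg(network)
  if (is.null(spec)) spec <- default_network_spec(network, dictionary$grid)
  scal_cols <- .scalar_cols(network)
  missing <- setdiff(c(scal_cols, spec$output_names),
                     colnames(dictionary$params))
  if (length(missing))
    stop("dictionary parameters lack columns required by the network: ",
         paste(missing, collapse = ", "))
  scalars <- dictionary$params[, scal_cols, drop = FALSE]
  scalar_scaling <- apply(scalars, 2, range)
  inputs <- with_local_seed(seed,
    .assemble_inputs(.dict_traj_list(dictionary), scalars, scalar_scaling,
                     noise_sigma))
  if (ncol(inputs) != spec$input_size)
    stop(sprintf("assembled input length %d does not match spec (%d)",
                 ncol(inputs), spec$input_size))
  targets <- .scale_targets(
    dictionary$params[, spec$output_names, drop = FALSE],
    spec$output_scaling)
  list(inputs = inputs, targets = targets, scalar_scaling = scalar_scaling,
       spec = spec)
}

# Noise -> M0 normalization -> unit norm -> concatenate scalars.
.assemble_inputs <- function(traj_list, scalars, scalar_scaling,
                             noise_sigma) {
  norm <- lapply(traj_list, function(m) {
    if (noise_sigma > 0) m <- add_noise(m, noise_sigma)
    l2_normalize(m)
  })
  sc <- .scale_scalars(scalars, scalar_scaling)
  do.call(cbind, c(norm, list(sc)))
}

.scale_scalars <- function(scalars, scaling) {
  out <- scalars
  for (j in seq_len(ncol(scalars))) {
    lo <- scaling[1, j]; hi <- scaling[2, j]
    out[, j] <- if (hi > lo) (scalars[, j] - lo) / (hi - lo) else 0.5
  }
  out
}

.scale_targets <- function(y, scaling) {
  out <- y
  for (j in seq_len(ncol(y)))
    out[, j] <- (y[, j] - scaling[1, j]) / (scaling[2, j] - scaling[1, j])
  out
}

.unscale_targets <- function(y, scaling) {
  out <- y
  for (j in seq_len(ncol(y)))
    out[, j] <- scaling[1, j] + y[, j] * (scaling[2, j] - scaling[1, j])
  out
}

# ---- minimal fully connected network with Adam -------------------------

.mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1]) *
                       sqrt(2 / sizes[l]), sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X) {
  L <- length(par$W)
  H <- X
  for (l in seq_len(L - 1)) {
    H <- H %*% par$W[[l]]
    H <- pmax(sweep_add(H, par$b[[l]]), 0)
  }
  Z <- sweep_add(H %*% par$W[[L]], par$b[[L]])
  1 / (1 + exp(-Z))
}

# Add a bias row-vector to every row (cheaper than sweep()).
sweep_add <- function(M, b) M + rep(b, each = nrow(M))

# Forward + backward pass; returns MSE loss and gradients.
.mlp_grad <- function(par, X, Y) {
  L <- length(par$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L - 1))
    acts[[l + 1]] <- pmax(sweep_add(acts[[l]] %*% par$W[[l]], par$b[[l]]), 0)
  out <- 1 / (1 + exp(-sweep_add(acts[[L]] %*% par$W[[L]], par$b[[L]])))
  err <- out - Y
  loss <- mean(err^2)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (2 / length(err)) * err * out * (1 - out)
  for (l in L:1) {
    dW[[l]] <- crossprod(acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, par$W[[l]])
      delta[acts[[l]] <= 0] <- 0
    }
  }
  list(loss = loss, dW = dW, db = db)
}

.adam_new <- function(par) {
  zero <- function(x) lapply(x, function(v) v * 0)
  list(mW = zero(par$W), vW = zero(par$W), mb = zero(par$b),
       vb = zero(par$b), t = 0)
}

.adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(par$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$dW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$dW[[l]]^2
    par$W[[l]] <- par$W[[l]] - lr * (st$mW[[l]] / c1) /
      (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$db[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$db[[l]]^2
    par$b[[l]] <- par$b[[l]] - lr * (st$mb[[l]] / c1) /
      (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(par = par, st = st)
}

#' Train a quantification network on a simulated dictionary
#'
#' Optimizes the fully connected network with Adam on minibatches of
#' noise-augmented dictionary rows (fresh noise every epoch), monitoring
#' mean squared error on a held-out validation split with early stopping.
#' Training is deterministic given `config$seed`.
#'
#' @param dictionary A [generate_dictionary()] result.
#' @param network `"mt"`, `"rnoe"` or `"amideglu"`.
#' @param config A [training_config()].
#' @param spec Optional [network_spec()] override.
#' @param verbose Print per-epoch validation loss.
#' @return An object of class `cest_net`: weights, spec, scalings, loss
#'   history, and the schedule hash(es) of the dictionary it was trained
#'   on (inference refuses data from a different schedule).
#' @export
train_cest_net <- function(dictionary, network = c("mt", "rnoe", "amideglu"),
                           config = training_config(), spec = NULL,
                           verbose = FALSE) {
  network <- match.arg(network)
  if (is.null(spec)) spec <- default_network_spec(network, dictionary$grid)
  scal_cols <- .scalar_cols(network)
  scalars <- dictionary$params[, scal_cols, drop = FALSE]
  scalar_scaling <- apply(scalars, 2, range)
  traj_list <- .dict_traj_list(dictionary)
  targets <- .scale_targets(
    dictionary$params[, spec$output_names, drop = FALSE],
    spec$output_scaling)
  n <- nrow(targets)
  with_local_seed(config$seed, {
    perm <- sample.int(n)
    n_val <- floor(config$validation_fraction * n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    trn_idx <- if (n_val > 0) perm[-seq_len(n_val)] else perm
    sub <- function(idx) list(
      traj = lapply(traj_list, function(m) m[idx, , drop = FALSE]),
      scalars = scalars[idx, , drop = FALSE],
      targets = targets[idx, , drop = FALSE])
    trn <- sub(rep(trn_idx, config$noise_copies))
    val <- sub(val_idx)
    # Per-feature standardization of the assembled inputs: normalized
    # trajectory entries vary by ~1e-3 around an O(0.2) mean, which
    # conditions the optimization very poorly at the fixed learning rate.
    # Center/scale are estimated once from a noisy realization of the
    # training inputs and stored with the model.
    X0 <- .assemble_inputs(trn$traj, trn$scalars, scalar_scaling,
                           config$noise_sigma)
    input_center <- colMeans(X0)
    input_scale <- pmax(apply(X0, 2, sd), 1e-8)
    std <- function(X) sweep_add(X, -input_center) *
      rep(1 / input_scale, each = nrow(X))
    # fixed noisy validation realization for a stable early-stopping signal
    Xval <- if (n_val > 0)
      std(.assemble_inputs(val$traj, val$scalars, scalar_scaling,
                           config$noise_sigma))
    par <- .mlp_init(c(spec$input_size, spec$hidden,
                       length(spec$output_names)))
    st <- .adam_new(par)
    best <- list(par = par, loss = Inf, epoch = 0)
    history <- numeric(0)
    n_trn <- nrow(trn$targets)
    nl <- config$noiseless_epochs %||% 0
    for (epoch in seq_len(config$epochs)) {
      sig <- if (epoch <= nl) 0 else config$noise_sigma
      X <- std(.assemble_inputs(trn$traj, trn$scalars, scalar_scaling,
                                sig))
      ord <- sample.int(n_trn)
      nb <- ceiling(n_trn / config$minibatch)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * config$minibatch + 1):
                     min(bi * config$minibatch, n_trn)]
        g <- .mlp_grad(par, X[idx, , drop = FALSE],
                       trn$targets[idx, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        upd <- .adam_step(par, g, st, config$learning_rate)
        par <- upd$par; st <- upd$st
      }
      vloss <- if (n_val > 0)
        mean((.mlp_forward(par, Xval) - val$targets)^2)
      else mean((.mlp_forward(par, X) - trn$targets)^2)
      history <- c(history, vloss)
      if (verbose)
        message(sprintf("epoch %3d  val MSE %.3e", epoch, vloss))
      if (vloss < best$loss || epoch <= nl)
        best <- list(par = par, loss = vloss, epoch = epoch)
      if (epoch > nl && epoch - best$epoch >= config$patience) break
    }
    structure(list(par = best$par, spec = spec,
                   input_center = input_center,
                   input_scale = input_scale,
                   scalar_scaling = scalar_scaling,
                   scalar_cols = scal_cols, network = network,
                   loss_history = history, best_epoch = best$epoch,
                   val_loss = best$loss, config = config,
                   schedule_hash = dictionary$schedule_hash),
              class = "cest_net")
  })
}

#' @export
print.cest_net <- function(x, ...) {
  cat(sprintf(
    "<cest_net> '%s': %d -> %s -> %d (%s); best val MSE %.3e (epoch %d/%d)\n",
    x$spec$name, x$spec$input_size,
    paste(x$spec$hidden, collapse = "-"), length(x$spec$output_names),
    paste(x$spec$output_names, collapse = ", "), x$val_loss, x$best_epoch,
    length(x$loss_history)))
  invisible(x)
}

#' Predict physical parameters from trajectories
#'
#' @param object A trained [train_cest_net()] model.
#' @param traj Raw trajectory matrix (rows = pixels, M0 first), or a list
#'   of two such matrices for the combined amide/glutamate network.
#' @param scalars Matrix of scalar inputs with the columns the model was
#'   trained on (water T1/T2 and, downstream, `f_ss`/`k_ssw`).
#' @param ... Unused.
#' @return Matrix of parameter estimates in physical units (columns follow
#'   the spec's `output_names`; every value lies within its scaling range).
#' @export
predict.cest_net <- function(object, traj, scalars, ...) {
  if (!is.list(traj)) traj <- list(traj)
  scalars <- as.matrix(scalars)
  missing <- setdiff(object$scalar_cols, colnames(scalars))
  if (length(missing))
    stop("missing scalar input(s): ", paste(missing, collapse = ", "))
  X <- .assemble_inputs(traj,
                        scalars[, object$scalar_cols, drop = FALSE],
                        object$scalar_scaling, noise_sigma = 0)
  if (ncol(X) != object$spec$input_size)
    stop("input size mismatch: expected ", object$spec$input_size)
  X <- sweep_add(X, -object$input_center) *
    rep(1 / object$input_scale, each = nrow(X))
  out <- .unscale_targets(.mlp_forward(object$par, X),
                          object$spec$output_scaling)
  colnames(out) <- object$spec$output_names
  out
}

#' Save or load a trained model archive
#'
#' The archive bundles weights, the network specification, input/output
#' scalings and the training schedule hash; loading verifies the class.
#'
#' @param model A `cest_net`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cest_net"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "cest_net"))
  x
}
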