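# Temporally regularized VAE + self-organizing-map clustering of trajectory
# windows.  The network is small enough (dense encoder/decoder, 4-dim latent,
# 36-node SOM) that forward/backward passes are hand-written matrix algebra;
# this keeps the package dependency-free and the training bit-reproducible
# for a given seed.

#' Convert a trajectory into the 7-feature series
#'
#' Feature order: center_x, center_y, nose_rel_x, nose_rel_y, tail_rel_x,
#' tail_rel_y, area.  Center coordinates are maze-center-referenced (the
#' trajectory convention); nose and tail are expressed relative to the body
#' center.  If `stats` (training-set means/SDs) is given, features are
#' z-standardized with it.
#'
#' @param traj a [trajectory()].
#' @param stats optional list `mean`, `sd` (length-7 each) of training
#'   statistics.
#' @return T x 7 numeric matrix.
#' @export
featurize <- function(traj, stats = NULL) {
  nl_assert(inherits(traj, "trajectory"), "traj must be a trajectory",
            "invalid_input")
  f <- cbind(traj$center[, 1], traj$center[, 2],
             traj$nose[, 1] - traj$center[, 1],
             traj$nose[, 2] - traj$center[, 2],
             traj$tail[, 1] - traj$center[, 1],
             traj$tail[, 2] - traj$center[, 2],
             traj$area)
  colnames(f) <- c("center_x", "center_y", "nose_rel_x", "nose_rel_y",
                   "tail_rel_x", "tail_rel_y", "area")
  if (!is.null(stats)) {
    f <- sweep(sweep(f, 2, stats$mean), 2, stats$sd, "/")
  }
  f
}

feature_stats <- function(feature_list) {
  all <- do.call(rbind, feature_list)
  list(mean = colMeans(all), sd = pmax(apply(all, 2, stats::sd), 1e-9))
}

#' De-standardize features
#'
#' Inverse of the affine standardization applied by [featurize()].
#'
#' @param f standardized feature matrix (or 3-D window array).
#' @param stats the `mean`/`sd` list used to standardize.
#' @return matrix/array in original units.
#' @export
destandardize <- function(f, stats) {
  if (length(dim(f)) == 3) {
    for (j in seq_along(stats$mean)) {
      f[, , j] <- f[, , j] * stats$sd[j] + stats$mean[j]
    }
    f
  } else {
    sweep(sweep(f, 2, stats$sd, "*"), 2, stats$mean, "+")
  }
}

#' Cut a feature series into overlapping fixed-length windows
#'
#' Windows of `win` seconds (100 time steps at 10 Hz) starting every `step`
#' seconds; a trailing partial window is dropped.
#'
#' @param features T x 7 matrix from [featurize()].
#' @param fs sampling rate, Hz.
#' @param win window length, seconds (default 10).
#' @param step window stride, seconds (default 1).
#' @return list `array` (N x steps x 7), `starts` (window start times, s);
#'   N = 0 with a warning when the series is shorter than one window.
#' @export
window_samples <- function(features, fs = 10, win = 10, step = 1) {
  len <- round(win * fs)
  stp <- max(1L, round(step * fs))
  n <- nrow(features)
  if (n < len) {
    warning("series shorter than one window; returning 0 samples")
    return(list(array = array(0, c(0, len, ncol(features))),
                starts = numeric(0)))
  }
  starts <- seq(1L, n - len + 1L, by = stp)
  arr <- array(0, c(length(starts), len, ncol(features)))
  for (i in seq_along(starts)) {
    arr[i, , ] <- features[starts[i]:(starts[i] + len - 1L), ]
  }
  list(array = arr, starts = (starts - 1L) / fs)
}

#' Build a windowed dataset from a set of maze trials
#'
#' Featurizes every trial, computes pooled standardization statistics,
#' windows each trial and concatenates samples with provenance.
#'
#' @param trials list of [trajectory()] objects (with `mouse`, `day`,
#'   `trial` set).
#' @param win,step window length and stride, seconds.
#' @param stats optional precomputed feature statistics (for applying a
#'   trained model to new data); computed from `trials` when `NULL`.
#' @return list of class `window_dataset`: `x` (N x (steps*7) matrix of
#'   flattened standardized windows), `dims` (steps, features), `meta`
#'   (data.frame mouse, day, trial, start, trial_key), `stats`, `step`.
#' @export
build_window_dataset <- function(trials, win = 10, step = 1, stats = NULL) {
  feats_raw <- lapply(trials, featurize)
  if (is.null(stats)) stats <- feature_stats(feats_raw)
  xs <- list(); meta <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    f <- sweep(sweep(feats_raw[[i]], 2, stats$mean), 2, stats$sd, "/")
    w <- suppressWarnings(window_samples(f, fs = tr$fs, win = win, step = step))
    if (!length(w$starts)) next
    n <- length(w$starts)
    xs[[length(xs) + 1]] <- matrix(w$array, nrow = n)
    meta[[length(meta) + 1]] <- data.frame(
      mouse = tr$mouse, day = tr$day, trial = tr$trial, start = w$starts,
      trial_key = paste(tr$mouse, tr$day, tr$trial, sep = "_"))
  }
  nl_assert(length(xs) > 0, "no trial produced any window", "insufficient_data")
  structure(list(x = do.call(rbind, xs),
                 dims = c(steps = round(win * trials[[1]]$fs), features = 7),
                 meta = do.call(rbind, meta), stats = stats, step = step),
            class = "window_dataset")
}

#' Training configuration for the behavioral cluster model
#'
#' @param latent_dim latent dimensionality (default 4).
#' @param som_rows,som_cols SOM grid shape (default 6 x 6 = 36 clusters).
#' @param hidden hidden layer width (default 128).
#' @param batch minibatch size (default 100).
#' @param epochs maximum training epochs (default 30, desk scale; the
#'   full-scale reference setting is 256).
#' @param patience early-stopping patience on validation reconstruction
#'   error, epochs.
#' @param lr Adam learning rate.
#' @param val_frac fraction of *trials* held out for validation (default
#'   0.15; the split is at trial granularity so overlapping windows never
#'   leak across the split).
#' @param w_recon,w_kl,w_som,w_smooth,w_pred loss weights (defaults 1, 1, 1,
#'   0.1, 0.1).  KL is scaled per input element so the default weights
#'   balance at these layer sizes.
#' @param sigma_start,sigma_end SOM neighborhood width (grid units),
#'   annealed geometrically across epochs.
#' @param seed training seed.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(latent_dim = 4, som_rows = 6, som_cols = 6,
                           hidden = 128, batch = 100, epochs = 30,
                           patience = 5, lr = 1e-3, val_frac = 0.15,
                           w_recon = 1, w_kl = 1, w_som = 1,
                           w_smooth = 0.1, w_pred = 0.1,
                           sigma_start = 2, sigma_end = 0.5, seed = 1L) {
  structure(as.list(environment()), class = "cluster_config")
}

init_params <- function(d_in, hidden, latent, k) {
  g <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(1 / c)), r, c)
  list(W1 = g(hidden, d_in), b1 = numeric(hidden),
       Wm = g(latent, hidden), bm = numeric(latent),
       Wv = g(latent, hidden), bv = rep(-2, latent),
       W4 = g(hidden, latent), b4 = numeric(hidden),
       W5 = g(d_in, hidden), b5 = numeric(d_in),
       E = matrix(stats::rnorm(k * latent, sd = 0.5), k, latent),
       A = diag(latent), cc = numeric(latent))
}

som_grid_dist2 <- function(rows, cols) {
  rc <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  outer(seq_len(rows * cols), seq_len(rows * cols), function(i, j) {
    (rc$r[i] - rc$r[j])^2 + (rc$c[i] - rc$c[j])^2
  })
}

bmu_of <- function(mu, E) {
  # squared distances B x K without loops
  d2 <- outer(rowSums(mu^2), rowSums(E^2), "+") - 2 * mu %*% t(E)
  max.col(-d2, ties.method = "first")
}

vae_forward <- function(p, X, eps = NULL) {
  H1 <- tanh(sweep(X %*% t(p$W1), 2, p$b1, "+"))
  mu <- sweep(H1 %*% t(p$Wm), 2, p$bm, "+")
  lv <- pmin(pmax(sweep(H1 %*% t(p$Wv), 2, p$bv, "+"), -10), 10)
  Z <- if (is.null(eps)) mu else mu + eps * exp(lv / 2)
  H2 <- tanh(sweep(Z %*% t(p$W4), 2, p$b4, "+"))
  Xh <- sweep(H2 %*% t(p$W5), 2, p$b5, "+")
  list(H1 = H1, mu = mu, lv = lv, Z = Z, H2 = H2, Xh = Xh)
}

# Composite loss and analytic gradients for one minibatch.
# X: B x D standardized windows; eps: B x L reparameterization noise;
# pairs: 2-column index matrix (rows of X that are temporally consecutive
# windows of the same trial).  w: list of loss weights.  sigma: current SOM
# neighborhood width; grid_d2: K x K squared grid distances.
vae_loss_grads <- function(p, X, eps, pairs, w, sigma, grid_d2) {
  B <- nrow(X); D <- ncol(X); L <- nrow(p$Wm)
  fw <- vae_forward(p, X, eps)
  H1 <- fw$H1; mu <- fw$mu; lv <- fw$lv; Z <- fw$Z; H2 <- fw$H2; Xh <- fw$Xh

  # reconstruction (per-element MSE)
  Rres <- Xh - X
  loss_rec <- w$w_recon * sum(Rres^2) / (B * D)
  dXh <- w$w_recon * 2 * Rres / (B * D)

  # KL to the standard normal, scaled per input element so default weights
  # balance against the reconstruction term
  elv <- exp(lv)
  loss_kl <- w$w_kl * sum(0.5 * (mu^2 + elv - 1 - lv)) / (B * D)
  dmu <- w$w_kl * mu / (B * D)
  dlv <- w$w_kl * 0.5 * (elv - 1) / (B * D)

  # SOM commitment with normalized Gaussian grid neighborhood of the BMU
  K <- nrow(p$E)
  bmu <- bmu_of(mu, p$E)
  Hmat <- exp(-grid_d2[bmu, , drop = FALSE] / (2 * sigma^2))
  Hmat <- Hmat / rowSums(Hmat)
  HE <- Hmat %*% p$E                       # B x L, neighborhood-mean codebook
  d2 <- outer(rowSums(mu^2), rowSums(p$E^2), "+") - 2 * mu %*% t(p$E)
  loss_som <- w$w_som * sum(Hmat * d2) / (B * L)
  dmu <- dmu + w$w_som * 2 * (mu - HE) / (B * L)
  dE <- w$w_som * 2 * (colSums(Hmat) * p$E - t(Hmat) %*% mu) / (B * L)

  # temporal smoothness + one-step linear latent forecast on consecutive pairs
  loss_sm <- 0; loss_pr <- 0
  dA <- matrix(0, L, L); dcc <- numeric(L)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    P <- nrow(pairs)
    a <- pairs[, 1]; b <- pairs[, 2]
    Dm <- mu[a, , drop = FALSE] - mu[b, , drop = FALSE]
    loss_sm <- w$w_smooth * sum(Dm^2) / (P * L)
    g <- w$w_smooth * 2 * Dm / (P * L)
    for (j in seq_len(L)) {
      dmu[, j] <- dmu[, j] +
        tabulate2(a, g[, j], B) - tabulate2(b, g[, j], B)
    }
    Pr <- sweep(mu[a, , drop = FALSE] %*% t(p$A), 2, p$cc, "+") -
      mu[b, , drop = FALSE]
    loss_pr <- w$w_pred * sum(Pr^2) / (P * L)
    gp <- w$w_pred * 2 * Pr / (P * L)
    dA <- t(gp) %*% mu[a, , drop = FALSE]
    dcc <- colSums(gp)
    gpa <- gp %*% p$A
    for (j in seq_len(L)) {
      dmu[, j] <- dmu[, j] +
        tabulate2(a, gpa[, j], B) - tabulate2(b, gp[, j], B)
    }
  }

  # backprop through the decoder into z, then into mu / logvar
  dW5 <- t(dXh) %*% H2; db5 <- colSums(dXh)
  dH2pre <- (dXh %*% p$W5) * (1 - H2^2)
  dW4 <- t(dH2pre) %*% Z; db4 <- colSums(dH2pre)
  dZ <- dH2pre %*% p$W4
  dmu <- dmu + dZ
  dlv <- dlv + dZ * eps * 0.5 * exp(lv / 2)

  dH1 <- dmu %*% p$Wm + dlv %*% p$Wv
  dH1pre <- dH1 * (1 - H1^2)
  grads <- list(
    W1 = t(dH1pre) %*% X, b1 = colSums(dH1pre),
    Wm = t(dmu) %*% H1, bm = colSums(dmu),
    Wv = t(dlv) %*% H1, bv = colSums(dlv),
    W4 = dW4, b4 = db4, W5 = dW5, b5 = db5,
    E = dE, A = dA, cc = dcc)
  list(loss = loss_rec + loss_kl + loss_som + loss_sm + loss_pr,
       parts = c(recon = loss_rec, kl = loss_kl, som = loss_som,
                 smooth = loss_sm, pred = loss_pr),
       grads = grads, recon_mse = sum(Rres^2) / (B * D))
}

# scatter-add: sum values v at integer positions idx into a length-n vector
tabulate2 <- function(idx, v, n) {
  out <- numeric(n)
  acc <- rowsum(v, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

consecutive_pairs <- function(meta, step) {
  same <- meta$trial_key[-nrow(meta)] == meta$trial_key[-1] &
    abs(meta$start[-1] - meta$start[-nrow(meta)] - step) < 1e-9
  cbind(which(same), which(same) + 1L)
}

#' Train the VAE + SOM behavioral cluster model
#'
#' Optimizes a composite loss by minibatch Adam: Gaussian-likelihood
#' reconstruction + KL (the ELBO), a SOM commitment loss over the codebook
#' with an annealed Gaussian grid neighborhood, a latent temporal-smoothness
#' penalty between consecutive windows, and a one-step linear latent
#' forecasting loss.  The train/validation split is at trial granularity
#' (85/15 by default) and early stopping tracks validation reconstruction
#' error.  Training is deterministic given `config$seed`.
#'
#' @param dataset a `window_dataset` from [build_window_dataset()] (>= 500
#'   samples).
#' @param config a [cluster_config()].
#' @return list of class `cluster_model`: `params`, `config`, `stats`
#'   (feature standardization), `grid` (SOM rows/cols), `val_mse`
#'   (best validation reconstruction MSE, standardized units), `history`.
#' @export
train_cluster_model <- function(dataset, config = cluster_config()) {
  nl_assert(inherits(dataset, "window_dataset"), "dataset must be a window_dataset")
  X <- dataset$x
  N <- nrow(X); D <- ncol(X)
  if (N < 500) nl_stop("need >= 500 window samples to train",
                       "insufficient_data")
  K <- config$som_rows * config$som_cols
  grid_d2 <- som_grid_dist2(config$som_rows, config$som_cols)
  w <- config[c("w_recon", "w_kl", "w_som", "w_smooth", "w_pred")]
  pairs_all <- consecutive_pairs(dataset$meta, dataset$step)

  with_seed(config$seed, {
    trials <- unique(dataset$meta$trial_key)
    n_val <- max(1L, round(config$val_frac * length(trials)))
    val_trials <- sample(trials, n_val)
    is_val <- dataset$meta$trial_key %in% val_trials
    tr_idx <- which(!is_val); va_idx <- which(is_val)
    nl_assert(length(tr_idx) >= config$batch,
              "too few training samples after the validation split",
              "insufficient_data")

    p <- init_params(D, config$hidden, config$latent_dim, K)
    state <- list(m = lapply(p, function(x) x * 0),
                  v = lapply(p, function(x) x * 0))
    # contiguous blocks preserve window adjacency inside each batch
    n_blocks <- ceiling(length(tr_idx) / config$batch)
    best <- list(val = Inf, p = p, epoch = 0L)
    history <- NULL
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      sigma <- config$sigma_start *
        (config$sigma_end / config$sigma_start)^((epoch - 1) /
                                                   max(1, config$epochs - 1))
      for (bi in sample(seq_len(n_blocks))) {
        rows <- tr_idx[((bi - 1) * config$batch + 1):
                         min(bi * config$batch, length(tr_idx))]
        if (length(rows) < 2) next
        Xb <- X[rows, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(rows) * config$latent_dim),
                      ncol = config$latent_dim)
        pos <- match(seq_len(nrow(X)), rows)
        pb <- pairs_all[!is.na(pos[pairs_all[, 1]]) &
                          !is.na(pos[pairs_all[, 2]]), , drop = FALSE]
        pb <- cbind(pos[pb[, 1]], pos[pb[, 2]])
        lg <- vae_loss_grads(p, Xb, eps, pb, w, sigma, grid_d2)
        if (!is.finite(lg$loss)) nl_stop("non-finite training loss",
                                         "training_failure")
        t_step <- t_step + 1L
        upd <- adam_step(p, lg$grads, state, config$lr, t_step)
        p <- upd$p; state <- upd$state
      }
      fwv <- vae_forward(p, X[va_idx, , drop = FALSE])  # deterministic z = mu
      val_mse <- mean((fwv$Xh - X[va_idx, , drop = FALSE])^2)
      history <- rbind(history, data.frame(epoch = epoch, sigma = sigma,
                                           train_loss = lg$loss,
                                           val_mse = val_mse))
      if (val_mse < best$val - 1e-9) {
        best <- list(val = val_mse, p = p, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) break
    }
  })
  structure(list(params = best$p, config = config, stats = dataset$stats,
                 grid = c(rows = config$som_rows, cols = config$som_cols),
                 val_mse = best$val, history = history,
                 dims = dataset$dims, step = dataset$step),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d clusters (%d x %d SOM), latent %d; val MSE %.4f\n",
              nrow(x$params$E), x$grid["rows"], x$grid["cols"],
              x$config$latent_dim, x$val_mse))
  invisible(x)
}

#' Save / load a cluster model checkpoint
#'
#' A checkpoint is a directory of parameter arrays (one CSV per matrix) plus
#' a JSON file holding the configuration, feature statistics and metadata —
#' plain text, portable, diffable.
#'
#' @param model a trained [train_cluster_model()] model.
#' @param path checkpoint directory (created if needed).
#' @return `load_cluster_model` returns a `cluster_model`.
#' @export
save_cluster_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(model$params)) {
    utils::write.csv(as.matrix(model$params[[nm]]),
                     file.path(path, paste0("param_", nm, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(config = unclass(model$config), stats = model$stats,
               grid = as.list(model$grid), val_mse = model$val_mse,
               dims = as.list(model$dims), step = model$step,
               vector_params = names(model$params)[
                 !vapply(model$params, is.matrix, logical(1))])
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cluster_model
#' @export
load_cluster_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  files <- list.files(path, pattern = "^param_", full.names = TRUE)
  params <- list()
  for (f in files) {
    nm <- sub("^param_(.*)\\.csv$", "\\1", basename(f))
    m <- as.matrix(utils::read.csv(f))
    dimnames(m) <- NULL
    params[[nm]] <- if (nm %in% meta$vector_params) as.numeric(m) else m
  }
  structure(list(params = params,
                 config = do.call(cluster_config, as.list(meta$config)),
                 stats = list(mean = as.numeric(meta$stats$mean),
                              sd = as.numeric(meta$stats$sd)),
                 grid = unlist(meta$grid), val_mse = meta$val_mse,
                 history = NULL, dims = unlist(meta$dims), step = meta$step),
            class = "cluster_model")
}

#' Assign windows to behavioral clusters
#'
#' Encodes each window to its posterior-mean latent and labels it with the
#' nearest SOM codebook node; per-trial occupancy is the fraction of that
#' trial's windows carrying each label (a probability vector over the
#' clusters).
#'
#' @param model a trained [train_cluster_model()] model.
#' @param dataset a `window_dataset` built with the *model's* feature
#'   statistics (pass `stats = model$stats` to [build_window_dataset()] for
#'   new data).
#' @return list of class `cluster_map`: `labels` (integer 1..K per window),
#'   `meta`, `occupancy` (trials x K matrix, rows on the simplex),
#'   `occupancy_meta` (mouse/day/trial per occupancy row).
#' @export
assign_clusters <- function(model, dataset) {
  nl_assert(inherits(model, "cluster_model"), "model must be a cluster_model")
  nl_assert(ncol(dataset$x) == ncol(model$params$W1),
            "feature/window shape differs from the trained model",
            "invalid_input")
  fw <- vae_forward(model$params, dataset$x)
  labels <- bmu_of(fw$mu, model$params$E)
  K <- nrow(model$params$E)
  keys <- unique(dataset$meta$trial_key)
  occ <- t(vapply(keys, function(k) {
    tabulate(labels[dataset$meta$trial_key == k], nbins = K)
  }, numeric(K)))
  occ <- occ / rowSums(occ)
  om <- dataset$meta[match(keys, dataset$meta$trial_key),
                     c("mouse", "day", "trial", "trial_key")]
  rownames(om) <- NULL
  structure(list(labels = labels, meta = dataset$meta, occupancy = occ,
                 occupancy_meta = om, latent = fw$mu),
            class = "cluster_map")
}

#' Reconstruct windows through the trained autoencoder
#'
#' Decodes the posterior-mean latent of each window and reports per-sample
#' and aggregate mean squared error in standardized units, plus the
#' reconstruction in original feature units.
#'
#' @param model a trained [train_cluster_model()] model.
#' @param dataset a `window_dataset` standardized with the model's
#'   statistics.
#' @return list: `recon` (N x steps x 7 array, original units),
#'   `mse_per_sample`, `mse` (aggregate, standardized units).
#' @export
reconstruct <- function(model, dataset) {
  nl_assert(inherits(model, "cluster_model") && !is.null(model$params),
            "model must be a trained cluster_model", "invalid_state")
  fw <- vae_forward(model$params, dataset$x)
  res <- (fw$Xh - dataset$x)^2
  arr <- array(fw$Xh, c(nrow(dataset$x), dataset$dims[1], dataset$dims[2]))
  list(recon = destandardize(arr, model$stats),
       mse_per_sample = rowMeans(res), mse = mean(res))
}
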