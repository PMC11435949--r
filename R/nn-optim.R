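## AdamW: Adam moment updates on the loss gradient with decoupled weight
## decay applied directly to the parameters (not folded into the gradient).

adamw_new <- function(layers, lr = 5e-3, weight_decay = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$lr <- lr; st$weight_decay <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st
}

adamw_step <- function(st, lr = st$lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$layers)) {
    l <- st$layers[[i]]
    if (length(l$params) == 0L) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      st$m[[i]][[nm]] <- b1 * st$m[[i]][[nm]] + (1 - b1) * g
      st$v[[i]][[nm]] <- b2 * st$v[[i]][[nm]] + (1 - b2) * g * g
      mh <- st$m[[i]][[nm]] / c1
      vh <- st$v[[i]][[nm]] / c2
      l$params[[nm]] <- l$params[[nm]] - lr * mh / (sqrt(vh) + st$eps) -
        lr * st$weight_decay * l$params[[nm]]
    }
  }
  invisible(st)
}

## deep-copy / restore of all parameters and normalisation statistics (used
## for best-checkpoint selection)
snapshot_params <- function(layers) {
  lapply(layers, function(l) {
    list(params = l$params, run_mean = l$run_mean, run_var = l$run_var)
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      layers[[i]]$run_mean <- snap[[i]]$run_mean
      layers[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(layers)
}
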