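# AdamW optimizer over a flat list of ad_param nodes.

optimizer_adamw <- function(params, lr = 0.01, betas = c(0.9, 0.999),
                            eps = 1e-8, weight_decay = 0) {
  stopifnot(length(params) > 0, all(vapply(params, is_ad, logical(1))))
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$b1 <- betas[1]
  opt$b2 <- betas[2]
  opt$eps <- eps
  opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim(p$value)))
  opt$v <- lapply(params, function(p) array(0, dim(p$value)))
  class(opt) <- "optimizer_adamw"
  opt
}

opt_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    # decoupled weight decay, applied before the adaptive step
    if (opt$wd > 0) p$value <- p$value - opt$lr * opt$wd * p$value
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

opt_zero <- function(opt) {
  for (p in opt$params) p$grad <- NULL
  invisible(opt)
}
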