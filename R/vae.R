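#' Summed diploid k-mer table of a sample
#'
#' Builds the per-sample VAE input: one k-mer count table summed over all
#' targets, with each target represented as a diploid. Heterozygous targets
#' contribute the sum of their two haplotype tables; homozygous targets twice
#' their single haplotype table (so homozygous and heterozygous targets carry
#' the same total count); targets with more than two haplotypes contribute
#' the sum of two haplotypes chosen uniformly at random (counts must stay
#' integral for the Poisson model, so averaging over all alleles is not an
#' option). Missing targets contribute nothing, i.e. zeroes. For a full
#' 62-target panel at ~160 bp the total is a little under 20,000.
#'
#' @param sample a `sample_genotypes`.
#' @param k k-mer length (default 8).
#' @return numeric vector of length 4^k of non-negative integer counts.
#'   The random choice at multi-allelic targets uses R's RNG; seed the
#'   session (or use the `seed` argument of [summed_diploid_tables()]) for
#'   reproducibility.
#' @export
summed_diploid_table <- function(sample, k = 8) {
  stopifnot(inherits(sample, "sample_genotypes"))
  counts <- numeric(4^k)
  for (t in names(sample$targets)) {
    haps <- sample$targets[[t]]
    use <- if (length(haps) == 1L) c(haps, haps)
           else if (length(haps) == 2L) haps
           else sample(haps, 2L)
    for (h in use) {
      kc <- kmer_counts(h, k)
      counts[kc$idx] <- counts[kc$idx] + kc$counts
    }
  }
  counts
}

#' Summed diploid tables for many samples
#'
#' @param genotypes list of `sample_genotypes`.
#' @param k k-mer length.
#' @param seed optional seed driving the random haplotype choice at
#'   multi-allelic targets (RNG state is restored afterwards).
#' @return matrix (samples x 4^k) with sample ids as rownames.
#' @export
summed_diploid_tables <- function(genotypes, k = 8, seed = NULL) {
  f <- function() {
    m <- t(vapply(genotypes, summed_diploid_table, numeric(4^k), k = k))
    rownames(m) <- vapply(genotypes, function(g) g$sample_id, character(1))
    m
  }
  if (is.null(seed)) f() else with_preserved_seed(seed, f())
}

## evaluate expr under a fixed seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Kullback-Leibler divergence between Poisson count vectors
#'
#' Divergence of independent Poisson distributions with means `x` (observed
#' counts) from those with means `lam` (reconstruction):
#' `sum(x*log(x/lam) + lam - x)` with `0*log(0) = 0`. Up to the additive
#' `log(x!)` constant this equals the negative Poisson log-likelihood of the
#' counts under the reconstruction, so minimising it maximises the
#' likelihood. Zero exactly when `lam == x` elementwise.
#'
#' @param x non-negative observed counts.
#' @param lam strictly positive predicted means.
#' @return non-negative number.
#' @export
poisson_divergence <- function(x, lam) {
  if (any(lam <= 0)) stop("predicted Poisson means must be strictly positive")
  if (any(x < 0)) stop("observed counts must be non-negative")
  pos <- x > 0
  sum(x[pos] * log(x[pos] / lam[pos])) + sum(lam) - sum(x)
}

#' Gaussian KL divergence from the standard normal
#'
#' KL divergence of a diagonal Gaussian `N(mu, diag(var))` from `N(0, I)`,
#' summed over latent dimensions: `sum(0.5*(mu^2 + var - log(var) - 1))`.
#' Zero exactly at `mu = 0`, `var = 1`. This is the latent regulariser: it
#' pulls encodings towards the origin and sets a natural scale.
#'
#' @param mu mean vector.
#' @param var variance vector (strictly positive).
#' @return non-negative number.
#' @export
gaussian_kl <- function(mu, var) {
  if (any(var <= 0)) stop("variances must be strictly positive")
  sum(0.5 * (mu^2 + var - log(var) - 1))
}

#' Combined VAE loss for one sample
#'
#' `poisson_divergence(x, lam) + w * gaussian_kl(mu, var)`; the batch loss
#' used in training is the mean of this over samples.
#'
#' @inheritParams poisson_divergence
#' @inheritParams gaussian_kl
#' @param w weight of the regularisation term (> 0 in training; 0 gives the
#'   pure reconstruction loss).
#' @return numeric loss.
#' @export
vae_loss <- function(x, lam, mu, var, w = 1) {
  poisson_divergence(x, lam) + w * gaussian_kl(mu, var)
}

#' VAE hyperparameter configuration
#'
#' @param latent_dim latent space dimension (default 3).
#' @param hidden encoder hidden layer sizes, mirrored in the decoder
#'   (default c(128, 32)).
#' @param w weight of the Gaussian KL regulariser (default 1).
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed for weight init, minibatch order and reparameterised
#'   sampling.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 3, hidden = c(128, 32), w = 1.0,
                       epochs = 200, batch_size = 32, lr = 1e-3, seed = 1) {
  stopifnot(latent_dim >= 1, w > 0 || w == 0, epochs >= 1, batch_size >= 1,
            lr > 0, length(hidden) >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), w = w,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "vae_config")
}

.softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
.sigmoid <- function(z) 1 / (1 + exp(-z))

.vae_init <- function(D, cfg, col_means) {
  sizes <- c(D, cfg$hidden)
  rnorm_mat <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(1 / c)), r, c)
  nh <- length(cfg$hidden)
  enc <- list(); dec <- list()
  for (i in seq_len(nh)) {
    enc[[i]] <- list(W = rnorm_mat(sizes[i + 1], sizes[i]),
                     b = numeric(sizes[i + 1]))
  }
  ## mirrored decoder: dec_in maps latent -> hidden[nh]; these map back up
  ## through the remaining hidden sizes; the output layer maps hidden[1] -> D
  for (i in seq_len(nh - 1L)) {
    dec[[i]] <- list(W = rnorm_mat(sizes[nh + 1 - i], sizes[nh + 2 - i]),
                     b = numeric(sizes[nh + 1 - i]))
  }
  hl <- cfg$hidden[nh]
  ## decoder output bias warm-started at the marginal mean rates
  out_b <- log(expm1(pmax(col_means, 1e-4)))
  list(enc = enc,
       mu = list(W = rnorm_mat(cfg$latent_dim, hl), b = numeric(cfg$latent_dim)),
       lv = list(W = rnorm_mat(cfg$latent_dim, hl), b = numeric(cfg$latent_dim)),
       dec_in = list(W = rnorm_mat(hl, cfg$latent_dim), b = numeric(hl)),
       dec = dec,
       out = list(W = rnorm_mat(D, sizes[2]), b = out_b))
}

## centre/scale raw count tables for the encoder: deviations from the
## training-set mean profile, scaled to a mean per-sample norm of 10. The
## count scale itself (~19,000 per sample) otherwise saturates the first
## tanh layer and erases between-sample differences; the reconstruction
## target stays raw counts.
.vae_scale_input <- function(x, center, scale) {
  sweep(x, 2, center) / scale
}

## encoder forward pass; returns hidden activations, MU and LV (log-variance)
.vae_encode <- function(par, X) {
  A <- list(.vae_scale_input(X, par$center, par$scale))
  for (l in par$enc) A[[length(A) + 1L]] <- tanh(sweep(A[[length(A)]] %*% t(l$W), 2, l$b, "+"))
  H <- A[[length(A)]]
  list(A = A,
       MU = sweep(H %*% t(par$mu$W), 2, par$mu$b, "+"),
       LV = sweep(H %*% t(par$lv$W), 2, par$lv$b, "+"))
}

## decoder forward pass from latent positions Z
.vae_decode <- function(par, Z) {
  Dacts <- list(tanh(sweep(Z %*% t(par$dec_in$W), 2, par$dec_in$b, "+")))
  for (l in par$dec) Dacts[[length(Dacts) + 1L]] <-
      tanh(sweep(Dacts[[length(Dacts)]] %*% t(l$W), 2, l$b, "+"))
  ZO <- sweep(Dacts[[length(Dacts)]] %*% t(par$out$W), 2, par$out$b, "+")
  list(Dacts = Dacts, ZO = ZO, LAM = .softplus(ZO) + 1e-8)
}

#' Train a variational autoencoder on summed diploid k-mer tables
#'
#' Fits a fully connected encoder/decoder pair: the encoder maps each
#' 4^8-dimensional count table to a diagonal Gaussian over the latent space
#' (mean and log-variance per dimension), a reparameterised point is sampled
#' from it (one draw per datapoint per step), and the decoder maps that point
#' back to strictly positive Poisson means via a softplus output activation.
#' The loss is the mean over samples of the Poisson reconstruction divergence
#' plus `w` times the Gaussian KL regulariser; optimisation is by Adam with
#' analytic gradients. Training is deterministic given `config$seed` (the
#' caller's RNG state is preserved).
#'
#' @param x numeric matrix (samples x 4^k) of summed diploid k-mer counts,
#'   as from [summed_diploid_tables()].
#' @param config a [vae_config()].
#' @return object of class `kmer_vae`: fitted weights, the config, the
#'   per-epoch mean training `loss` trajectory, and `latent` (training-set
#'   latent means and variances).
#' @export
train_vae <- function(x, config = vae_config()) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (any(x < 0)) stop("count tables must be non-negative")
  with_preserved_seed(config$seed, {
    n <- nrow(x); D <- ncol(x); w <- config$w
    par <- .vae_init(D, config, colMeans(x))
    par$center <- colMeans(x)
    par$scale <- max(mean(sqrt(rowSums(sweep(x, 2, par$center)^2))) / 10,
                     1e-8)
    adam <- list(m = rapply(par, function(p) p * 0, how = "replace"),
                 v = rapply(par, function(p) p * 0, how = "replace"),
                 t = 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    losses <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        X <- x[idx, , drop = FALSE]
        B <- nrow(X)
        enc <- .vae_encode(par, X)
        EPS <- matrix(stats::rnorm(B * config$latent_dim), B)
        SD <- exp(enc$LV / 2)
        Z <- enc$MU + SD * EPS
        dec <- .vae_decode(par, Z)
        LAM <- dec$LAM
        pos <- X > 0
        recon <- sum(X[pos] * log(X[pos] / LAM[pos])) + sum(LAM) - sum(X)
        kl <- 0.5 * sum(enc$MU^2 + exp(enc$LV) - enc$LV - 1)
        loss <- (recon + w * kl) / B
        if (!is.finite(loss))
          stop("non-finite VAE loss at epoch ", epoch,
               " (recon = ", signif(recon, 4), ", kl = ", signif(kl, 4), ")")
        epoch_loss <- epoch_loss + loss * B / n
        ## ---- backward ----
        g <- list()
        dZO <- ((1 - X / LAM) / B) * .sigmoid(dec$ZO)
        Dlast <- dec$Dacts[[length(dec$Dacts)]]
        g$out <- list(W = crossprod(dZO, Dlast), b = colSums(dZO))
        dH <- dZO %*% par$out$W
        nh <- length(par$dec)
        g$dec <- vector("list", nh)
        for (i in rev(seq_len(nh))) {
          Ai <- dec$Dacts[[i + 1L]]
          dZi <- dH * (1 - Ai^2)
          Aprev <- dec$Dacts[[i]]
          g$dec[[i]] <- list(W = crossprod(dZi, Aprev), b = colSums(dZi))
          dH <- dZi %*% par$dec[[i]]$W
        }
        dZ1d <- dH * (1 - dec$Dacts[[1L]]^2)
        g$dec_in <- list(W = crossprod(dZ1d, Z), b = colSums(dZ1d))
        dZ <- dZ1d %*% par$dec_in$W
        dMU <- dZ + w * enc$MU / B
        dLV <- dZ * 0.5 * SD * EPS + w * 0.5 * (exp(enc$LV) - 1) / B
        H <- enc$A[[length(enc$A)]]
        g$mu <- list(W = crossprod(dMU, H), b = colSums(dMU))
        g$lv <- list(W = crossprod(dLV, H), b = colSums(dLV))
        dA <- dMU %*% par$mu$W + dLV %*% par$lv$W
        g$enc <- vector("list", length(par$enc))
        for (i in rev(seq_along(par$enc))) {
          Ai <- enc$A[[i + 1L]]
          dZi <- dA * (1 - Ai^2)
          g$enc[[i]] <- list(W = crossprod(dZi, enc$A[[i]]), b = colSums(dZi))
          dA <- dZi %*% par$enc[[i]]$W
        }
        ## ---- Adam ----
        adam$t <- adam$t + 1
        upd <- function(p, gp, mp, vp) {
          mp <- b1 * mp + (1 - b1) * gp
          vp <- b2 * vp + (1 - b2) * gp^2
          mh <- mp / (1 - b1^adam$t)
          vh <- vp / (1 - b2^adam$t)
          list(p = p - config$lr * mh / (sqrt(vh) + eps), m = mp, v = vp)
        }
        walk <- function(path) {
          u <- upd(par[[path]]$W, g[[path]]$W, adam$m[[path]]$W, adam$v[[path]]$W)
          par[[path]]$W <<- u$p; adam$m[[path]]$W <<- u$m; adam$v[[path]]$W <<- u$v
          u <- upd(par[[path]]$b, g[[path]]$b, adam$m[[path]]$b, adam$v[[path]]$b)
          par[[path]]$b <<- u$p; adam$m[[path]]$b <<- u$m; adam$v[[path]]$b <<- u$v
        }
        for (i in seq_along(par$enc)) {
          u <- upd(par$enc[[i]]$W, g$enc[[i]]$W, adam$m$enc[[i]]$W, adam$v$enc[[i]]$W)
          par$enc[[i]]$W <- u$p; adam$m$enc[[i]]$W <- u$m; adam$v$enc[[i]]$W <- u$v
          u <- upd(par$enc[[i]]$b, g$enc[[i]]$b, adam$m$enc[[i]]$b, adam$v$enc[[i]]$b)
          par$enc[[i]]$b <- u$p; adam$m$enc[[i]]$b <- u$m; adam$v$enc[[i]]$b <- u$v
        }
        for (i in seq_along(par$dec)) {
          u <- upd(par$dec[[i]]$W, g$dec[[i]]$W, adam$m$dec[[i]]$W, adam$v$dec[[i]]$W)
          par$dec[[i]]$W <- u$p; adam$m$dec[[i]]$W <- u$m; adam$v$dec[[i]]$W <- u$v
          u <- upd(par$dec[[i]]$b, g$dec[[i]]$b, adam$m$dec[[i]]$b, adam$v$dec[[i]]$b)
          par$dec[[i]]$b <- u$p; adam$m$dec[[i]]$b <- u$m; adam$v$dec[[i]]$b <- u$v
        }
        for (nm in c("mu", "lv", "dec_in", "out")) walk(nm)
      }
      losses[epoch] <- epoch_loss
    }
    fit <- structure(list(par = par, config = config, loss = losses,
                          input_dim = D, sample_ids = rownames(x)),
                     class = "kmer_vae")
    fit$latent <- encode_means(fit, x)
    fit
  })
}

#' @export
print.kmer_vae <- function(x, ...) {
  cfg <- x$config
  cat("k-mer VAE: ", x$input_dim, " -> ",
      paste(cfg$hidden, collapse = " -> "), " -> ", cfg$latent_dim,
      "-d latent (w = ", cfg$w, ", ", cfg$epochs, " epochs)\n",
      "  final epoch-mean training loss: ", signif(x$loss[length(x$loss)], 6),
      "\n", sep = "")
  invisible(x)
}

#' Encode samples at their latent means
#'
#' Deterministic projection of count tables to the latent space: the
#' encoder's mean position per sample (used for classification), with the
#' per-dimension variances retained for reporting.
#'
#' @param model a trained `kmer_vae`.
#' @param x matrix (samples x 4^k) of summed diploid k-mer counts.
#' @return data.frame: `sample_id`, `mu1..mud`, `var1..vard`.
#' @export
encode_means <- function(model, x) {
  stopifnot(inherits(model, "kmer_vae"))
  if (ncol(x) != model$input_dim)
    stop("table length ", ncol(x), " does not match the model's input dim ",
         model$input_dim)
  enc <- .vae_encode(model$par, x)
  d <- model$config$latent_dim
  out <- data.frame(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    stringsAsFactors = FALSE)
  for (j in seq_len(d)) out[[paste0("mu", j)]] <- enc$MU[, j]
  for (j in seq_len(d)) out[[paste0("var", j)]] <- exp(enc$LV[, j])
  out
}

#' @export
predict.kmer_vae <- function(object, newdata, type = c("latent", "response"),
                             ...) {
  type <- match.arg(type)
  if (type == "latent") return(encode_means(object, newdata))
  enc <- .vae_encode(object$par, newdata)
  .vae_decode(object$par, enc$MU)$LAM
}

#' @export
plot.kmer_vae <- function(x, dims = c(1, 2), labels = NULL, ...) {
  mu <- as.matrix(x$latent[, paste0("mu", dims)])
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  plot(mu, col = col, pch = 19,
       xlab = paste("latent", dims[1]), ylab = paste("latent", dims[2]), ...)
  invisible(x)
}

#' Latent positions as TSV
#'
#' @param latent data.frame from [encode_means()].
#' @param path output path.
#' @export
write_latent_positions <- function(latent, path) {
  utils::write.table(latent, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
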