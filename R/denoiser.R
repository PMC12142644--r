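#' Denoiser network configuration
#'
#' The noise-prediction network is a 1-D UNet-style autoencoder over feature
#' vectors: three downsampling blocks (layer normalization, then affine maps
#' of the current representation and of the composite steering embedding to
#' the block width, summed, passed through a sigmoid-linear-unit activation
#' and one further affine enrichment), a stack of residual blocks at the
#' bottleneck width, and three mirrored upsampling blocks whose inputs are
#' concatenated with the matching down-path activation (skip connections)
#' before the block affine. The composite embedding is the sum of a
#' sinusoidal encoding of `t / T` and an affine embedding of the
#' conditioning `[i_s; l]`.
#'
#' @param d feature dimension.
#' @param n_labels label vector length.
#' @param down_sizes output widths of the downsampling blocks
#'   (default `c(512, 256, 128)`).
#' @param n_residual number of residual blocks at the bottleneck (default 2);
#'   their width is `down_sizes[length(down_sizes)]`.
#' @param up_sizes output widths of the upsampling blocks; defaults to the
#'   mirror of `down_sizes` ending at `d`.
#' @param embed_dim width of the composite embedding (even; default 128,
#'   matching the residual width).
#' @return object of class `denoiser_config`.
#' @export
denoiser_config <- function(d, n_labels,
                            down_sizes = c(512L, 256L, 128L),
                            n_residual = 2L,
                            up_sizes = c(rev(down_sizes)[-1], d),
                            embed_dim = 128L) {
  if (embed_dim %% 2 != 0) rlang::abort("`embed_dim` must be even (paired sin/cos).")
  if (length(up_sizes) != length(down_sizes) ||
      up_sizes[length(up_sizes)] != d) {
    rlang::abort("`up_sizes` must mirror `down_sizes` and end at `d`.")
  }
  if (n_residual < 0) rlang::abort("`n_residual` must be nonnegative.")
  structure(list(d = as.integer(d), n_labels = as.integer(n_labels),
                 cond_dim = as.integer(d + n_labels),
                 down_sizes = as.integer(down_sizes),
                 n_residual = as.integer(n_residual),
                 up_sizes = as.integer(up_sizes),
                 embed_dim = as.integer(embed_dim)),
            class = "denoiser_config")
}

# Block input widths implied by a config: down path starts at d; the up path
# starts at the bottleneck width; skips pair each up block with the down-path
# activation produced at its mirror depth (the raw input for the last one).
config_dims <- function(config) {
  nd <- length(config$down_sizes)
  down_in <- c(config$d, config$down_sizes[-nd])
  up_in <- c(config$down_sizes[nd], config$up_sizes[-nd])
  skip <- c(rev(config$down_sizes[-nd]), config$d)
  list(down_in = down_in, down_out = config$down_sizes,
       up_in = up_in, up_out = config$up_sizes, skip = skip)
}

#' Initialize denoiser parameters
#'
#' Weights use fan-in-scaled Gaussian initialization (`sd = 1/sqrt(fan_in)`),
#' biases start at zero, layer-norm gains at one.
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed; initialization is reproducible.
#' @return named list of parameter arrays (class `denoiser_state`).
#' @export
init_denoiser <- function(config, seed = 1L) {
  dm <- config_dims(config)
  m <- config$embed_dim
  withr::with_seed(seed, {
    p <- list(cond_W = rand_mat(config$cond_dim, m), cond_b = numeric(m))
    for (j in seq_along(dm$down_in)) {
      p[[paste0("down", j, "_g")]] <- rep(1, dm$down_in[j])
      p[[paste0("down", j, "_bln")]] <- numeric(dm$down_in[j])
      p[[paste0("down", j, "_Wx")]] <- rand_mat(dm$down_in[j], dm$down_out[j])
      p[[paste0("down", j, "_We")]] <- rand_mat(m, dm$down_out[j])
      p[[paste0("down", j, "_b")]] <- numeric(dm$down_out[j])
      p[[paste0("down", j, "_Wr")]] <- rand_mat(dm$down_out[j], dm$down_out[j])
      p[[paste0("down", j, "_br")]] <- numeric(dm$down_out[j])
    }
    w <- config$down_sizes[length(config$down_sizes)]
    for (i in seq_len(config$n_residual)) {
      p[[paste0("res", i, "_W1")]] <- rand_mat(w, w)
      p[[paste0("res", i, "_b1")]] <- numeric(w)
      p[[paste0("res", i, "_W2")]] <- rand_mat(w, w)
      p[[paste0("res", i, "_b2")]] <- numeric(w)
    }
    for (j in seq_along(dm$up_in)) {
      p[[paste0("up", j, "_g")]] <- rep(1, dm$up_in[j])
      p[[paste0("up", j, "_bln")]] <- numeric(dm$up_in[j])
      p[[paste0("up", j, "_Wx")]] <- rand_mat(dm$up_in[j] + dm$skip[j], dm$up_out[j])
      p[[paste0("up", j, "_We")]] <- rand_mat(m, dm$up_out[j])
      p[[paste0("up", j, "_b")]] <- numeric(dm$up_out[j])
      p[[paste0("up", j, "_Wr")]] <- rand_mat(dm$up_out[j], dm$up_out[j])
      p[[paste0("up", j, "_br")]] <- numeric(dm$up_out[j])
    }
    structure(p, class = "denoiser_state", config = config)
  })
}

rand_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)), n_in, n_out)
}

#' Count trainable parameters
#' @param state a `denoiser_state`.
#' @return integer total over all arrays.
#' @export
n_params <- function(state) sum(vapply(state, length, integer(1)))

#' Sinusoidal time-step embedding
#'
#' The step is first normalized to `x = t / T`, then encoded as
#' `[sin(x * f_1..f_H), cos(x * f_1..f_H)]` with `H = embed_dim / 2`
#' geometrically spaced frequencies `f_i = 10000^((i-1)/H)`.
#'
#' @param t step index (scalar or vector), in `1..n_steps`.
#' @param n_steps total diffusion steps `T`.
#' @param embed_dim even embedding width.
#' @return matrix `length(t) x embed_dim` (or a vector for scalar `t`).
#' @export
time_embed <- function(t, n_steps, embed_dim) {
  if (embed_dim %% 2 != 0) rlang::abort("`embed_dim` must be even (paired sin/cos).")
  if (any(t < 1) || any(t > n_steps)) rlang::abort("Step index out of range.")
  half <- embed_dim / 2
  freqs <- 10000 ^ ((seq_len(half) - 1) / half)
  ang <- outer(t / n_steps, freqs)
  out <- cbind(sin(ang), cos(ang))
  if (length(t) == 1L) drop(out) else out
}

#' Conditioning embedding
#'
#' Affine map of the concatenated conditioning `[i_s; l]` to the embedding
#' width; the caller sums it with [time_embed()] to form the composite
#' steering embedding.
#'
#' @param i_s conditioning features (vector or `n x d` matrix).
#' @param l labels (vector or `n x n_labels` matrix).
#' @param W weight matrix `(d + n_labels) x embed_dim` (e.g. `state$cond_W`).
#' @param b bias vector of length `embed_dim`.
#' @return matrix `n x embed_dim` (or vector for vector input).
#' @export
condition_embed <- function(i_s, l, W, b) {
  vec_in <- !is.matrix(i_s)
  i_s <- if (vec_in) matrix(i_s, nrow = 1) else i_s
  l <- if (is.matrix(l)) l else matrix(l, nrow = nrow(i_s), byrow = TRUE,
                                       ncol = length(l))
  C <- cbind(i_s, l)
  if (ncol(C) != nrow(W)) rlang::abort("Conditioning width does not match `W`.")
  out <- add_bias(C %*% W, b)
  if (vec_in) drop(out) else out
}

silu <- function(u) u * stats::plogis(u)
silu_grad <- function(u) { s <- stats::plogis(u); s * (1 + u * (1 - s)) }
add_bias <- function(M, b) sweep(M, 2, b, "+")

layernorm_fwd <- function(h, g, b, eps = 1e-5) {
  mu <- rowMeans(h)
  xc <- h - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(h)), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  p <- ncol(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dx <- cache$inv / p *
    (p * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

# Full forward pass. X: n x d noisy input, tvec: per-row step indices,
# IS: n x d conditioning features, L: n x n_labels. Returns the prediction
# and, when cache = TRUE, everything backward() needs.
denoiser_forward <- function(state, config, X, tvec, IS, L, n_steps,
                             cache = FALSE) {
  dm <- config_dims(config)
  n <- nrow(X)
  Et <- time_embed(tvec, n_steps, config$embed_dim)
  if (!is.matrix(Et)) Et <- matrix(Et, nrow = 1)
  Cin <- cbind(IS, L)
  E <- Et + add_bias(Cin %*% state$cond_W, state$cond_b)

  cc <- list(Cin = Cin, E = E)
  H <- X
  down_out <- vector("list", length(dm$down_in))
  for (j in seq_along(dm$down_in)) {
    nm <- paste0("down", j, "_")
    ln <- layernorm_fwd(H, state[[paste0(nm, "g")]], state[[paste0(nm, "bln")]])
    U <- add_bias(ln$out %*% state[[paste0(nm, "Wx")]] +
                    E %*% state[[paste0(nm, "We")]], state[[paste0(nm, "b")]])
    A <- silu(U)
    Hn <- add_bias(A %*% state[[paste0(nm, "Wr")]], state[[paste0(nm, "br")]])
    if (cache) cc[[nm]] <- list(h_in = H, ln = ln, U = U, A = A)
    down_out[[j]] <- Hn
    H <- Hn
  }
  for (i in seq_len(config$n_residual)) {
    nm <- paste0("res", i, "_")
    U1 <- add_bias(H %*% state[[paste0(nm, "W1")]], state[[paste0(nm, "b1")]])
    A1 <- silu(U1)
    U2 <- add_bias(A1 %*% state[[paste0(nm, "W2")]], state[[paste0(nm, "b2")]])
    A2 <- silu(U2)
    if (cache) cc[[nm]] <- list(h_in = H, U1 = U1, A1 = A1, U2 = U2)
    H <- H + A2
  }
  nd <- length(dm$down_in)
  skips <- c(rev(down_out[-nd]), list(X))
  for (j in seq_along(dm$up_in)) {
    nm <- paste0("up", j, "_")
    ln <- layernorm_fwd(H, state[[paste0(nm, "g")]], state[[paste0(nm, "bln")]])
    Cc <- cbind(ln$out, skips[[j]])
    U <- add_bias(Cc %*% state[[paste0(nm, "Wx")]] +
                    E %*% state[[paste0(nm, "We")]], state[[paste0(nm, "b")]])
    A <- silu(U)
    Hn <- add_bias(A %*% state[[paste0(nm, "Wr")]], state[[paste0(nm, "br")]])
    if (cache) cc[[nm]] <- list(h_in = H, ln = ln, C = Cc, U = U, A = A)
    H <- Hn
  }
  if (any(!is.finite(H))) rlang::abort("Non-finite values in denoiser output.")
  if (cache) list(out = H, cache = cc) else list(out = H)
}

# Backward pass for the mean-squared denoising loss. dOut is dL/d(output).
# Returns gradients with the same names/shapes as `state`.
denoiser_backward <- function(state, config, cc, dOut) {
  dm <- config_dims(config)
  grads <- list()
  dE <- matrix(0, nrow(dOut), config$embed_dim)
  nd <- length(dm$down_in)
  dSkip <- vector("list", length(dm$up_in))

  affine_block_bwd <- function(nm, cache, dY, input_mat) {
    # shared tail of down/up blocks: U -> A=silu(U) -> Hn = A Wr + br
    dA <- dY %*% t(state[[paste0(nm, "Wr")]])
    grads[[paste0(nm, "Wr")]] <<- t(cache$A) %*% dY
    grads[[paste0(nm, "br")]] <<- colSums(dY)
    dU <- dA * silu_grad(cache$U)
    grads[[paste0(nm, "b")]] <<- colSums(dU)
    grads[[paste0(nm, "Wx")]] <<- t(input_mat) %*% dU
    grads[[paste0(nm, "We")]] <<- t(cc$E) %*% dU
    dE <<- dE + dU %*% t(state[[paste0(nm, "We")]])
    dU %*% t(state[[paste0(nm, "Wx")]])
  }

  dH <- dOut
  for (j in rev(seq_along(dm$up_in))) {
    nm <- paste0("up", j, "_")
    cj <- cc[[nm]]
    dC <- affine_block_bwd(nm, cj, dH, cj$C)
    p_in <- dm$up_in[j]
    dHN <- dC[, seq_len(p_in), drop = FALSE]
    dSkip[[j]] <- dC[, -seq_len(p_in), drop = FALSE]
    lb <- layernorm_bwd(dHN, cj$ln, state[[paste0(nm, "g")]])
    grads[[paste0(nm, "g")]] <- lb$dg
    grads[[paste0(nm, "bln")]] <- lb$db
    dH <- lb$dx
  }

  for (i in rev(seq_len(config$n_residual))) {
    nm <- paste0("res", i, "_")
    ci <- cc[[nm]]
    dA2 <- dH
    dU2 <- dA2 * silu_grad(ci$U2)
    grads[[paste0(nm, "W2")]] <- t(ci$A1) %*% dU2
    grads[[paste0(nm, "b2")]] <- colSums(dU2)
    dA1 <- dU2 %*% t(state[[paste0(nm, "W2")]])
    dU1 <- dA1 * silu_grad(ci$U1)
    grads[[paste0(nm, "W1")]] <- t(ci$h_in) %*% dU1
    grads[[paste0(nm, "b1")]] <- colSums(dU1)
    dH <- dH + dU1 %*% t(state[[paste0(nm, "W1")]])
  }

  # up block j consumed the output of down block (nd - j) as its skip; the
  # final up block consumed the raw input (gradient not needed further).
  for (j in rev(seq_along(dm$down_in))) {
    nm <- paste0("down", j, "_")
    cj <- cc[[nm]]
    if (j < nd) dH <- dH + dSkip[[nd - j]]
    dHN <- affine_block_bwd(nm, cj, dH, cj$ln$out)
    lb <- layernorm_bwd(dHN, cj$ln, state[[paste0(nm, "g")]])
    grads[[paste0(nm, "g")]] <- lb$dg
    grads[[paste0(nm, "bln")]] <- lb$db
    dH <- lb$dx
  }

  grads$cond_W <- t(cc$Cin) %*% dE
  grads$cond_b <- colSums(dE)
  grads[names(state)]
}

#' Predict the noise component of a noised sample
#'
#' Runs the denoiser forward: given the noisy state `x_t`, the step `t`, and
#' the conditioning (baseline features `i_s` and labels `l`), returns the
#' network's estimate of the Gaussian noise that was mixed into `x_t`.
#' Deterministic given `(state, inputs)`.
#'
#' @param x_t noisy features (vector or `n x d` matrix).
#' @param t step index (scalar or one per row), in `1..n_steps`.
#' @param i_s conditioning features (vector or matrix).
#' @param l conditioning labels (vector or matrix).
#' @param state a `denoiser_state` from [init_denoiser()].
#' @param config the matching [denoiser_config()]; defaults to the config the
#'   state was initialized with.
#' @param n_steps total diffusion steps used to normalize `t` (default 100).
#' @return predicted noise, same shape as `x_t`.
#' @export
predict_noise <- function(x_t, t, i_s, l, state,
                          config = attr(state, "config"), n_steps = 100L) {
  vec_in <- !is.matrix(x_t)
  X <- if (vec_in) matrix(x_t, nrow = 1) else x_t
  IS <- if (is.matrix(i_s)) i_s else matrix(i_s, nrow = nrow(X), byrow = TRUE,
                                            ncol = length(i_s))
  L <- if (is.matrix(l)) l else matrix(l, nrow = nrow(X), byrow = TRUE,
                                       ncol = length(l))
  if (ncol(X) != config$d || ncol(IS) != config$d || ncol(L) != config$n_labels) {
    rlang::abort("Input widths do not match the denoiser configuration.")
  }
  if (length(t) == 1L) t <- rep(t, nrow(X))
  out <- denoiser_forward(state, config, X, t, IS, L, n_steps)$out
  if (vec_in) drop(out) else out
}

#' Wrap a trained state as a denoiser closure for sampling
#' @param state a `denoiser_state`.
#' @param config the matching config (defaults to the state's).
#' @param n_steps total diffusion steps (default 100).
#' @return function `(x_t, t, i_s, l) -> eps_hat` for [diffusion_sample()].
#' @export
as_denoiser <- function(state, config = attr(state, "config"), n_steps = 100L) {
  function(x_t, t, i_s, l) predict_noise(x_t, t, i_s, l, state, config, n_steps)
}
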