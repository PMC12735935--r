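#' Multi-block regularized generalized canonical correlation analysis
#'
#' Iterative ascent algorithm maximizing
#' sum_{j != k} c_jk g(cov(X_j w_j, X_k w_k)) with full shrinkage (tau = 1),
#' i.e. a covariance (PLS-like) criterion with unit-Euclidean-norm weight
#' vectors. `scheme` selects g: "horst" (g = x), "factorial" (g = x^2) or
#' "centroid" (g = |x|). Successive components are obtained by deflating
#' each block against its own canonical variate; initialization is the
#' deterministic leading right singular vector of each block. A block with
#' fewer columns than `k` retains only as many components as it has columns
#' (a one-column block contributes a single variate).
#'
#' @param blocks list of `block_matrix` objects or bare matrices sharing the
#'   subject (row) dimension; expected z-scored.
#' @param k number of components per block (default 3).
#' @param tau regularization per block; only tau = 1 (full shrinkage) is
#'   implemented, matching the covariance criterion.
#' @param scheme scheme function g.
#' @param connectivity symmetric 0/1 design matrix with zero diagonal;
#'   default full off-diagonal connectivity.
#' @param max_iter,tol inner-loop controls; convergence is declared when the
#'   relative criterion increment falls below `tol`.
#' @return an `rgcca_model`: per block weight matrices (features x k_b) and
#'   canonical variates (subjects x k_b), the per-component criterion
#'   traces, convergence flags, and block metadata.
#' @export
fit_rgcca <- function(blocks, k = 3, tau = 1,
                      scheme = c("factorial", "horst", "centroid"),
                      connectivity = NULL, max_iter = 1000, tol = 1e-8) {
  scheme <- match.arg(scheme)
  if (abs(tau - 1) > 1e-12)
    stopf("only tau = 1 (covariance criterion) is implemented")
  X <- lapply(blocks, function(b) if (inherits(b, "block_matrix")) b$data else b)
  B <- length(X)
  if (B < 2) stopf("need >= 2 blocks")
  n <- nrow(X[[1]])
  if (any(vapply(X, nrow, 0L) != n)) stopf("blocks must share the subject dimension")
  if (is.null(connectivity)) {
    connectivity <- matrix(1, B, B); diag(connectivity) <- 0
  }
  if (!isSymmetric(connectivity) || any(diag(connectivity) != 0))
    stopf("connectivity must be symmetric with zero diagonal")
  gprime <- switch(scheme,
                   horst = function(x) rep(1, length(x)),
                   factorial = function(x) 2 * x,
                   centroid = function(x) sign(x))
  gfun <- switch(scheme,
                 horst = identity,
                 factorial = function(x) x^2,
                 centroid = abs)
  k_b <- pmin(k, vapply(X, ncol, 0L))
  weights <- lapply(seq_len(B), function(j)
    matrix(NA_real_, ncol(X[[j]]), k_b[j]))
  variates <- lapply(seq_len(B), function(j) matrix(NA_real_, n, k_b[j]))
  traces <- vector("list", max(k_b))
  converged <- logical(max(k_b))
  Xd <- X  # deflated working copies
  for (comp in seq_len(max(k_b))) {
    active <- which(k_b >= comp)
    w <- lapply(active, function(a) {
      v <- svd(Xd[[a]], nu = 0, nv = 1)$v[, 1]
      v / sqrt(sum(v^2))
    })
    names(w) <- as.character(active)
    y <- lapply(seq_along(active), function(i) Xd[[active[i]]] %*% w[[i]])
    crit_of <- function(y) {
      tot <- 0
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (i == j) next
        cjk <- connectivity[active[i], active[j]]
        if (cjk != 0)
          tot <- tot + cjk * gfun(crossprod(y[[i]], y[[j]])[1] / (n - 1))
      }
      tot
    }
    crit <- crit_of(y)
    trace <- crit
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      for (i in seq_along(active)) {
        z <- numeric(n)
        for (j in seq_along(active)) {
          if (i == j) next
          cjk <- connectivity[active[i], active[j]]
          if (cjk == 0) next
          cv <- crossprod(y[[i]], y[[j]])[1] / (n - 1)
          z <- z + cjk * gprime(cv) * y[[j]]
        }
        wnew <- crossprod(Xd[[active[i]]], z)
        nrm <- sqrt(sum(wnew^2))
        if (nrm < .Machine$double.eps) next  # isolated/degenerate block
        w[[i]] <- wnew / nrm
        y[[i]] <- Xd[[active[i]]] %*% w[[i]]
      }
      crit_new <- crit_of(y)
      trace <- c(trace, crit_new)
      if (abs(crit_new - crit) < tol * max(1, abs(crit_new))) {
        conv <- TRUE; crit <- crit_new; break
      }
      crit <- crit_new
    }
    if (!conv) warnf("RGCCA component %d: no convergence in %d iterations", comp, max_iter)
    traces[[comp]] <- trace
    converged[comp] <- conv
    for (i in seq_along(active)) {
      a <- active[i]
      weights[[a]][, comp] <- w[[i]]
      variates[[a]][, comp] <- y[[i]]
      # deflate the block against its own variate
      yy <- sum(y[[i]]^2)
      if (yy > 0)
        Xd[[a]] <- Xd[[a]] - y[[i]] %*% (crossprod(y[[i]], Xd[[a]]) / yy)
    }
  }
  modalities <- vapply(seq_len(B), function(j) {
    b <- blocks[[j]]
    if (inherits(b, "block_matrix")) b$modality else sprintf("block%d", j)
  }, "")
  structure(
    list(weights = weights, variates = variates, k_per_block = k_b,
         modalities = modalities, scheme = scheme, tau = tau,
         connectivity = connectivity, traces = traces,
         converged = converged, n_subjects = n),
    class = "rgcca_model")
}

#' Outer average variance explained per component and block
#'
#' The outer AVE of component j in block b is the mean over the block's
#' features of the squared Pearson correlation between the feature column
#' and the block's j-th canonical variate, in percent. Constant features
#' contribute 0. A cumulative table is attached.
#'
#' @param model an `rgcca_model`.
#' @param blocks the blocks the model was fitted on.
#' @return an `ave_table`: components x blocks matrix of outer AVE (%),
#'   with a `cross_block_mean` column-wise mean per component and a
#'   `cumulative` attribute.
#' @export
compute_ave <- function(model, blocks) {
  X <- lapply(blocks, function(b) if (inherits(b, "block_matrix")) b$data else b)
  B <- length(X)
  kmax <- max(model$k_per_block)
  ave <- matrix(NA_real_, kmax, B,
                dimnames = list(sprintf("comp%d", seq_len(kmax)), model$modalities))
  for (b in seq_len(B)) {
    for (j in seq_len(model$k_per_block[b])) {
      y <- model$variates[[b]][, j]
      r2 <- apply(X[[b]], 2, function(col) {
        if (stats::sd(col) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps)
          return(0)
        stats::cor(col, y)^2
      })
      ave[j, b] <- 100 * mean(r2)
    }
  }
  cbm <- rowMeans(ave, na.rm = TRUE)
  structure(ave, cross_block_mean = cbm,
            cumulative = apply(ave, 2, function(col) cumsum(ifelse(is.na(col), 0, col))),
            class = c("ave_table", "matrix"))
}

#' Choose the number of retained components from an AVE profile
#'
#' Default "fixed" rule returns `k` (three components per block is the
#' conventional parsimony point for this pipeline). The "marginal" rule
#' returns the smallest k such that the (k+1)-th component's cross-block
#' mean AVE falls below `threshold` percentage points (diminishing
#' returns).
#'
#' @param ave an `ave_table` (or a numeric vector of per-component
#'   cross-block mean AVEs for the marginal rule).
#' @param rule "fixed" or "marginal".
#' @param k fixed number of components.
#' @param threshold marginal AVE threshold in percentage points.
#' @return integer number of components.
#' @export
select_n_components <- function(ave, rule = c("fixed", "marginal"),
                                k = 3, threshold = 5) {
  rule <- match.arg(rule)
  if (rule == "fixed") return(as.integer(k))
  marg <- if (inherits(ave, "ave_table")) attr(ave, "cross_block_mean") else as.numeric(ave)
  below <- which(marg < threshold)
  if (length(below) == 0) return(length(marg))
  as.integer(max(1L, below[1] - 1L))
}

#' Concatenate canonical variates into the joint multimodal matrix
#'
#' Column-wise concatenation in block order (block 1 components 1..k_1,
#' block 2 components 1..k_2, ...), each variate standardized to unit
#' sample variance. Column provenance (block, component) is retained.
#'
#' @param model an `rgcca_model`.
#' @return a subjects x sum(k_b) matrix with a `provenance` attribute.
#' @export
concatenate_variates <- function(model) {
  cols <- list(); prov <- list()
  for (b in seq_along(model$variates)) {
    for (j in seq_len(model$k_per_block[b])) {
      y <- model$variates[[b]][, j]
      s <- stats::sd(y)
      cols[[length(cols) + 1]] <- if (s > .Machine$double.eps) y / s else y
      prov[[length(prov) + 1]] <- data.frame(block = model$modalities[b],
                                             component = j)
    }
  }
  J <- do.call(cbind, cols)
  prov <- do.call(rbind, prov)
  colnames(J) <- sprintf("%s_c%d", prov$block, prov$component)
  attr(J, "provenance") <- prov
  J
}

#' Joint independent component analysis of the concatenated variates
#'
#' Symmetric fixed-point ICA with the logcosh contrast on the joint
#' subjects x variates matrix. Subjects are the sample dimension: columns
#' are centered, the matrix is whitened through its SVD, and an orthogonal
#' unmixing matrix is estimated from a seeded random orthogonal start. The
#' decomposition is joint = loading %*% source, where the subject loadings
#' (subjects x n_ic, unit variance) are the statistically independent
#' subject-mode components and each source row is the corresponding pattern
#' over the concatenated canonical variates. Components are ordered by
#' decreasing explained variance (source-row energy) and signed so each
#' source's largest-magnitude element is positive. If the requested number
#' of components exceeds the matrix's effective rank it is reduced with a
#' warning (a redundant one-column block therefore lowers the IC count).
#'
#' @param joint subjects x variates matrix.
#' @param n_ic number of components; default = effective rank (at most
#'   min(subjects - 1, columns)).
#' @param seed integer seed for the orthogonal start.
#' @param max_iter,tol fixed-point controls.
#' @return a `jica_model`: `source` (n_ic x variates), `loading`
#'   (subjects x n_ic), `unmixing`, `center`, `n_ic`, `converged`.
#' @export
fit_jica <- function(joint, n_ic = NULL, seed = 1L, max_iter = 1000,
                     tol = 1e-9) {
  n <- nrow(joint); p <- ncol(joint)
  center <- colMeans(joint)
  Xc <- sweep(joint, 2, center)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(n, p) * .Machine$double.eps * sv$d[1])
  cap <- min(n - 1L, p, rank)
  if (is.null(n_ic)) n_ic <- cap
  if (n_ic > cap) {
    warnf("n_ic reduced from %d to effective rank %d", n_ic, cap)
    n_ic <- cap
  }
  m <- n_ic
  # whitened subject-mode candidates: Z has orthonormal columns * sqrt(n-1),
  # i.e. unit sample variance and zero correlation
  Um <- sv$u[, seq_len(m), drop = FALSE]
  Z <- Um * sqrt(n - 1)                       # n x m
  set.seed(child_seed(seed, 6L))
  W <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                       m, m) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    S <- Z %*% t(W)                           # n x m candidate components
    G <- tanh(S)
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), m, m) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warnf("jICA: no convergence in %d iterations", max_iter)
  A <- Z %*% t(W)                             # n x m independent loadings
  # source rows expressing Xc = A %*% src: src = t(A) Xc / (n-1) since
  # A's columns are orthonormal * sqrt(n-1)
  src <- crossprod(A, Xc) / (n - 1)           # m x p
  # order by decreasing explained variance (source-row energy); sign so the
  # largest-|.| source element is positive
  ord <- order(rowSums(src^2), decreasing = TRUE)
  src <- src[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]
  for (i in seq_len(m)) {
    s <- sign(src[i, which.max(abs(src[i, ]))])
    if (s < 0) { src[i, ] <- -src[i, ]; A[, i] <- -A[, i]; W[i, ] <- -W[i, ] }
  }
  rownames(src) <- colnames(A) <- sprintf("IC%d", seq_len(m))
  colnames(src) <- colnames(joint)
  rownames(A) <- rownames(joint)
  structure(list(source = src, loading = A, unmixing = W, center = center,
                 n_ic = m, converged = converged),
            class = "jica_model")
}

#' Two-stage multimodal fusion
#'
#' Runs the full fusion chain: multi-block RGCCA (tau = 1), outer-AVE
#' computation, canonical-variate concatenation, and joint ICA, returning
#' the per-subject independent-component scores alongside every
#' intermediate model. Five 3-component blocks yield 15 ICs; adding a
#' one-column behavioral block (e.g. GOS-E) contributes a single variate
#' and yields 16.
#'
#' @param blocks list of z-scored `block_matrix` objects (>= 2).
#' @param k components per block.
#' @param n_ic number of ICs; default = number of concatenated variates
#'   (reduced to effective rank if needed).
#' @param seed integer seed (ICA start).
#' @param scheme,connectivity,max_iter,tol passed to [fit_rgcca()].
#' @return a `fusion_result`: rgcca model, `ave` table, `joint` matrix,
#'   `jica` model, and `scores` (subjects x ICs data.frame).
#' @export
fuse <- function(blocks, k = 3, n_ic = NULL, seed = 1L,
                 scheme = "factorial", connectivity = NULL,
                 max_iter = 1000, tol = 1e-8) {
  if (length(blocks) < 2) stopf("need >= 2 blocks")
  model <- fit_rgcca(blocks, k = k, scheme = scheme,
                     connectivity = connectivity, max_iter = max_iter,
                     tol = tol)
  ave <- compute_ave(model, blocks)
  J <- concatenate_variates(model)
  if (is.null(n_ic)) n_ic <- ncol(J)
  jica <- fit_jica(J, n_ic = n_ic, seed = seed)
  scores <- as.data.frame(jica$loading)
  scores <- cbind(data.frame(id = rownames(J) %||% sprintf("sub-%03d", seq_len(nrow(J)))),
                  scores)
  rownames(scores) <- NULL
  structure(list(rgcca = model, ave = ave, joint = J, jica = jica,
                 scores = scores, n_ic = jica$n_ic),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result: %d blocks -> %d variates -> %d ICs over %d subjects\n",
              length(x$rgcca$variates), ncol(x$joint), x$n_ic,
              x$rgcca$n_subjects))
  invisible(x)
}
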