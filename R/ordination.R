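.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), computed between
#' all sample pairs of an abundance table. Bounded in [0, 1]; a semimetric
#' (the triangle inequality need not hold).
#'
#' @param abund a \linkS4class{SampleTable} or non-negative numeric matrix
#'   (samples x taxa).
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames. A pair of all-zero samples has undefined dissimilarity; it
#'   is set to 0 with a warning.
#' @export
brayCurtis <- function(abund) {
  x <- if (is(abund, "SampleTable")) tableValues(abund) else as.matrix(abund)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative abundances")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      tot <- sum(x[i, ] + x[j, ])
      if (tot == 0) {
        if (!warned) {
          warning("all-zero sample pair; Bray-Curtis undefined, set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / tot
      }
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical (Torgerson) scaling of a dissimilarity matrix: double-centre
#' -1/2 J D^2 J, eigendecompose, and scale eigenvectors by the square roots
#' of the positive eigenvalues. No correction is applied for negative
#' eigenvalues; they are reported and their axes dropped.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @param n_axes number of axes to return (default 2); truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return An \linkS4class{OrdinationResult}.
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("at least two samples required")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix not symmetric")
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- which(sc$eig > sqrt(.Machine$double.eps) * max(abs(sc$eig)))
  npos <- length(pos)
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalue axes available; truncating")
    n_axes <- npos
  }
  coords <- sc$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("A", seq_len(n_axes))
  rownames(coords) <- rownames(d)
  pos_eig <- sc$eig[sc$eig > 0]
  new("OrdinationResult", coordinates = coords, eigenvalues = eig,
      proportionExplained = pos_eig[seq_len(n_axes)] / sum(pos_eig))
}

#' Fit environmental vectors onto an ordination
#'
#' For each environmental variable (e.g. a metabolite concentration),
#' least-squares fits the variable on the ordination axes; r2 is the
#' squared multiple correlation, the direction is the normalised
#' coefficient vector, and significance comes from permuting the
#' variable's values across samples:
#' p = (1 + #\{permuted r2 >= observed\}) / (1 + n_perm).
#'
#' @param ord an \linkS4class{OrdinationResult}.
#' @param env a \linkS4class{SampleTable} (concentrations) or numeric
#'   matrix; rows must align with the ordination samples (matched by row
#'   name when both are named).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutations (recommended; required
#'   for reproducible pipelines).
#' @return data.frame with one row per variable: \code{variable},
#'   \code{r2}, \code{p}, and direction components \code{A1}, \code{A2},
#'   ... Constant variables get r2 = 0, p = 1 and NA direction, with a
#'   warning.
#' @export
envFit <- function(ord, env, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  X <- ordCoordinates(ord)
  E <- if (is(env, "SampleTable")) tableValues(env) else as.matrix(env)
  if (nrow(E) != nrow(X)) stop("env rows must align with ordination samples")
  if (!is.null(rownames(E)) && !is.null(rownames(X))) {
    if (!setequal(rownames(E), rownames(X)))
      stop("env sample ids do not match ordination sample ids")
    E <- E[rownames(X), , drop = FALSE]
  }
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Xc))
  k <- ncol(X)
  .withSeed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    res <- lapply(colnames(E), function(v) {
      y <- E[, v]
      yc <- y - mean(y)
      ss <- sum(yc^2)
      if (ss == 0) {
        warning("constant environmental variable '", v, "'; r2 = 0")
        return(c(r2 = 0, p = 1, stats::setNames(rep(NA_real_, k),
                                                colnames(X))))
      }
      r2 <- sum((crossprod(Q, yc))^2) / ss
      b <- qr.coef(qr(Xc), yc)
      dir <- b / sqrt(sum(b^2))
      Yp <- matrix(yc[perms], nrow = n)
      r2p <- colSums(crossprod(Q, Yp)^2) / ss
      p <- (1 + sum(r2p >= r2 - 1e-12)) / (1 + n_perm)
      c(r2 = r2, p = p, stats::setNames(dir, colnames(X)))
    })
  })
  out <- as.data.frame(do.call(rbind, res))
  data.frame(variable = colnames(E), out, row.names = NULL,
             check.names = FALSE)
}
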