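#' Fit a two-class Fisher linear discriminant in closed form
#'
#' Maximizes the Fisher criterion — squared projected mean separation over
#' summed within-class scatter — whose maximizer is
#' \code{w ∝ (S0 + S1)⁻¹ (mu0 - mu1)}, with \code{S_j} the un-normalized
#' scatter matrices (sums of outer products of deviations from the class
#' mean). The returned w is unit-norm; the decision threshold is the
#' midpoint projection \code{wᵀ(mu0 + mu1)/2} (equal-prior rule — the design
#' is class-balanced).
#'
#' @param features n x d numeric matrix of feature vectors.
#' @param labels Length-n vector with exactly two distinct values; the
#'   smaller (after sorting) plays the role of class 0.
#' @param ridge Nonnegative ridge added to S0 + S1 as \code{ridge * I} before
#'   solving. \code{NULL} (default) uses \code{1e-10 * mean(diag(S0 + S1))}
#'   for numerical safety; pass 0 for the exact unregularized solve.
#'
#' @return An object of class \code{lda_model}: \code{w}, \code{mu0},
#'   \code{mu1}, \code{S0}, \code{S1}, \code{threshold}, \code{class_labels}
#'   (the two labels, class-0 role first).
#' @export
lda_fit <- function(features, labels, ridge = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("exactly two classes required")
  i0 <- labels == lv[1L]
  if (sum(i0) < 2L || sum(!i0) < 2L)
    stop("each class needs at least 2 samples")

  scatter <- function(X) {
    mu <- colMeans(X)
    dev <- sweep(X, 2L, mu)
    list(mu = mu, S = crossprod(dev))
  }
  c0 <- scatter(features[i0, , drop = FALSE])
  c1 <- scatter(features[!i0, , drop = FALSE])
  Sw <- c0$S + c1$S
  if (is.null(ridge)) ridge <- 1e-10 * mean(diag(Sw))
  if (ridge < 0) stop("ridge must be nonnegative")
  Sw_r <- Sw + diag(ridge, ncol(features))

  rhs <- c0$mu - c1$mu
  if (sqrt(sum(rhs^2)) == 0)
    stop("identical class means: no discriminative direction exists")
  w <- tryCatch(solve(Sw_r, rhs), error = function(e)
    stop("singular within-class scatter; refit with ridge > 0", call. = FALSE))
  w <- w / sqrt(sum(w^2))

  structure(list(w = w, mu0 = c0$mu, mu1 = c1$mu, S0 = c0$S, S1 = c1$S,
                 threshold = sum(w * (c0$mu + c1$mu)) / 2,
                 class_labels = lv),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> d = ", length(x$w), ", classes: ",
      paste(x$class_labels, collapse = " vs "),
      ", threshold = ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Classify feature vectors with a fitted discriminant
#'
#' A point is assigned the class-0 label iff its projection \code{wᵀx} lies
#' on class 0's side of the threshold; a point projecting exactly onto the
#' threshold goes to class 0 (documented tie rule).
#'
#' @param model An \code{lda_model}.
#' @param features m x d matrix (or a single length-d vector).
#' @return Length-m vector of predicted labels (values from
#'   \code{model$class_labels}).
#' @export
lda_predict <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != length(model$w))
    stop("feature dimension does not match the model")
  proj <- drop(features %*% model$w)
  side0 <- sum(model$w * model$mu0) >= model$threshold
  is0 <- if (side0) proj >= model$threshold else proj <= model$threshold
  ifelse(is0, model$class_labels[1L], model$class_labels[2L])
}

#' Fisher criterion of a candidate direction
#'
#' Evaluates the objective the discriminant maximizes:
#' \code{(wᵀ(mu0 - mu1))² / (wᵀ S0 w + wᵀ S1 w)}. Scale-invariant in w;
#' used by property tests to confirm the fitted w is the maximizer.
#'
#' @param model An \code{lda_model}.
#' @param w_test Candidate direction (length d, nonzero).
#' @return The scalar ratio.
#' @export
fisher_ratio <- function(model, w_test) {
  if (length(w_test) != length(model$w)) stop("dimension mismatch")
  g1 <- drop(t(w_test) %*% (model$S0 + model$S1) %*% w_test)
  if (g1 <= 0) stop("within-class spread along w_test is zero")
  g2 <- (sum(w_test * (model$mu0 - model$mu1)))^2
  g2 / g1
}

#' Serialize an LDA model to JSON
#' @param model An \code{lda_model}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_lda_model <- function(model, path) {
  jsonlite::write_json(
    list(w = model$w, mu0 = model$mu0, mu1 = model$mu1,
         threshold = model$threshold, class_labels = model$class_labels),
    path, digits = NA)
  invisible(path)
}
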