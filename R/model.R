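# JTT substitution model with discrete-gamma rate variation and invariant
# sites.
#
# The published Jones-Taylor-Thornton exchangeabilities and equilibrium
# frequencies are read from phangorn, which ships them; the rate matrix
# assembly, spectral decomposition, and the +G/+I mixture are implemented
# here. Amino-acid order follows the conventional ARNDCQEGHILKMFPSTWYV.

.aa_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.jtt_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      j <- utils::getFromNamespace(".JTT", "phangorn")
      ex <- matrix(0, 20, 20, dimnames = list(.aa_order, .aa_order))
      ex[lower.tri(ex)] <- j$Q
      ex <- ex + t(ex)
      bf <- as.numeric(j$bf)
      names(bf) <- .aa_order
      cache <<- list(exchangeabilities = ex, frequencies = bf / sum(bf))
    }
    cache
  }
})

#' Mean rates of the discrete-gamma categories
#'
#' Category rates are the means of K equal-probability slices of the
#' Gamma(alpha, alpha) distribution (mean 1), so the average relative
#' rate across categories is exactly 1 for any shape.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories.
#' @return Numeric vector of K category rates.
#' @export
gamma_category_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                          rate = alpha)
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

#' JTT substitution model with +G and +I
#'
#' Assembles the reversible JTT rate matrix `Q[a,b] = s[a,b] * pi[b]`,
#' scaled to one expected substitution per site per unit branch length,
#' and prepares its spectral decomposition for fast transition
#' probabilities. Rate variation across sites is a mixture of K
#' equal-weight discrete-gamma categories plus an invariant class of
#' weight `p_inv` (rate 0); gamma category rates are not rescaled by
#' `1/(1 - p_inv)`, so the total expected rate is `(1 - p_inv)`.
#'
#' @param gamma_shape gamma shape alpha (default 2.4398).
#' @param n_categories number of gamma categories K (default 5).
#' @param p_inv proportion of invariant sites in [0, 1) (default 0.0727).
#' @return Object of class `lp_model`.
#' @export
substitution_model <- function(gamma_shape = 2.4398, n_categories = 5L,
                               p_inv = 0.0727) {
  stopifnot(gamma_shape > 0, n_categories >= 1, p_inv >= 0, p_inv < 1)
  jtt <- .jtt_data()
  pi <- jtt$frequencies
  ex <- jtt$exchangeabilities
  Q <- ex * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))        # symmetric similarity transform
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(exchangeabilities = ex, frequencies = pi, Q = Q,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 p_inv = p_inv,
                 category_rates = gamma_category_rates(gamma_shape,
                                                       n_categories),
                 eig_values = eig$values,
                 eig_left = (1 / sq) * eig$vectors,       # diag(1/sq) %*% V
                 eig_right = t(sq * eig$vectors)),        # t(V) %*% diag(sq)
            class = "lp_model")
}

#' @export
print.lp_model <- function(x, ...) {
  cat("<lp_model> JTT + G(", x$n_categories, ", alpha = ", x$gamma_shape,
      ") + I(", x$p_inv, ")\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model an `lp_model`.
#' @param t branch length in expected substitutions per site (>= 0).
#' @param rate relative site rate multiplying `t`.
#' @return 20 x 20 matrix of `P(a -> b; rate * t)` with amino-acid
#'   dimnames.
#' @export
transition_prob <- function(model, t, rate = 1) {
  stopifnot(t >= 0, rate >= 0)
  P <- model$eig_left %*% (exp(model$eig_values * t * rate) *
                             model$eig_right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(.aa_order, .aa_order)
  P
}
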