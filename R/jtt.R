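# Canonical one-letter amino-acid ordering used throughout (PAML convention).
AA_LEVELS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# JTT integer exchangeabilities (lower triangle, column-major over AA_LEVELS)
# and equilibrium frequencies, as published for the Jones-Taylor-Thornton
# empirical amino-acid model.
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194,
  378, 475, 9, 11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38,
  646, 44, 5, 74, 101, 64, 126, 20, 17, 528, 34, 86, 58, 81, 391,
  47, 12, 263, 30, 10, 15, 503, 232, 8, 70, 16, 10, 49, 767, 130,
  112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5, 59, 69, 17,
  23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55,
  8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25,
  52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226,
  24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQ <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

.jtt_cache <- new.env(parent = emptyenv())

.jtt_build <- function() {
  if (!is.null(.jtt_cache$eig)) return(invisible(NULL))
  pi0 <- .JTT_FREQ / sum(.JTT_FREQ)
  S <- matrix(0, 20, 20, dimnames = list(AA_LEVELS, AA_LEVELS))
  S[lower.tri(S)] <- .JTT_EXCH
  S <- S + t(S)
  Q <- S * rep(pi0, each = 20)        # Q[i, j] = S[i, j] * pi[j], i != j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi0 * diag(Q))           # expected substitutions/site at rate 1
  Q <- Q / mu                         # normalized to 1 substitution/site
  # symmetrize for a numerically stable eigendecomposition:
  # B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric for reversible Q
  sq <- sqrt(pi0)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  .jtt_cache$pi <- pi0
  .jtt_cache$Q <- Q
  # P(t) = D^-1 V exp(L t) V' D  with D = diag(sqrt(pi))
  .jtt_cache$left <- (1 / sq) * eig$vectors          # D^-1 V
  .jtt_cache$right <- t(eig$vectors * sq)            # V' D
  .jtt_cache$lambda <- eig$values
  invisible(NULL)
}

#' JTT equilibrium amino-acid frequencies
#'
#' Stationary frequencies of the Jones-Taylor-Thornton empirical substitution
#' model, in the canonical ARNDCQEGHILKMFPSTWYV order.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
jtt_frequencies <- function() {
  .jtt_build()
  stats::setNames(.jtt_cache$pi, AA_LEVELS)
}

#' JTT instantaneous rate matrix
#'
#' The reversible 20x20 rate matrix of the JTT model, normalized so the
#' expected number of substitutions per site per unit time equals 1.
#'
#' @return 20x20 numeric matrix with amino-acid dimnames; rows sum to 0.
#' @export
jtt_rate_matrix <- function() {
  .jtt_build()
  .jtt_cache$Q
}

#' JTT transition probability matrix
#'
#' Computes P(t) = exp(Qt) for the normalized JTT rate matrix via the cached
#' eigendecomposition of its symmetrized form.
#'
#' @param t Branch length in expected substitutions per site (scalar, >= 0).
#' @return 20x20 stochastic matrix; `P[i, j]` is the probability that state i
#'   is observed as j after time t.
#' @export
jtt_transition_prob <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  .jtt_build()
  P <- .jtt_cache$left %*% (exp(.jtt_cache$lambda * t) * .jtt_cache$right)
  # clip tiny negative round-off so downstream logs are safe
  P[P < 0] <- 0
  dimnames(P) <- list(AA_LEVELS, AA_LEVELS)
  P
}

# integer state encoding of an amino-acid character vector; NA for gaps /
# unknown characters (treated as missing data by the likelihood machinery)
aa_to_state <- function(chars) {
  match(toupper(chars), AA_LEVELS)
}
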