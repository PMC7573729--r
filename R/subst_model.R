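#' Time-reversible substitution models with rate heterogeneity
#'
#' Builds a normalized rate matrix Q from symmetric exchangeabilities and
#' state frequencies, together with a discrete-gamma + invariant-sites rate
#' mixture. Supported kinds:
#' \describe{
#'   \item{JC69}{4 nucleotide states, equal frequencies, equal rates.}
#'   \item{GTR}{4 nucleotide states; exchangeabilities and frequencies are
#'     inputs (defaults: all exchangeabilities 1, equal frequencies, i.e.
#'     JC-like until configured).}
#'   \item{JTT}{20 amino-acid states with the published
#'     Jones–Taylor–Thornton exchangeabilities and frequencies.}
#' }
#' Q is scaled so the expected substitution rate at equilibrium is one
#' (`-sum(pi * diag(Q)) == 1`), making branch lengths expected
#' substitutions per site.
#'
#' @param kind `"JC69"`, `"GTR"` or `"JTT"`.
#' @param freq state frequencies (simplex). Defaults: equal (JC69/GTR) or
#'   the published JTT frequencies.
#' @param exch symmetric exchangeability matrix with positive off-diagonal
#'   entries (GTR only; ignored for JC69/JTT).
#' @param alpha gamma shape for among-site rate variation (> 0).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param k number of discrete gamma categories (>= 1). `k = 1` means no
#'   gamma variation.
#' @return object of class `subst_model`: `kind`, `states`, `freq`, `Q`,
#'   eigen-decomposition cache, `rates` (category rates, mean 1), `p_inv`.
#' @export
subst_model <- function(kind = c("JC69", "GTR", "JTT"), freq = NULL,
                        exch = NULL, alpha = 1, p_inv = 0, k = 4L) {
  kind <- match.arg(kind)
  stopifnot(alpha > 0, p_inv >= 0, p_inv < 1, k >= 1)
  if (kind == "JTT") {
    jtt <- utils::getFromNamespace(".JTT", "phangorn")  # published JTT counts
    states <- core_states("amino-acid")
    s <- matrix(0, 20, 20)
    s[lower.tri(s)] <- jtt$Q
    s <- s + t(s)
    if (is.null(freq)) freq <- jtt$bf
  } else {
    states <- core_states("nucleotide")
    if (kind == "JC69") {
      s <- matrix(1, 4, 4)
      freq <- rep(0.25, 4)
    } else {
      s <- if (is.null(exch)) matrix(1, 4, 4) else as.matrix(exch)
      if (is.null(freq)) freq <- rep(0.25, 4)
    }
  }
  n <- length(states)
  stopifnot(nrow(s) == n, isTRUE(all.equal(s, t(s))),
            all(s[upper.tri(s)] > 0),
            length(freq) == n, all(freq > 0))
  freq <- freq / sum(freq)
  Q <- s * rep(freq, each = n)     # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  # reversible Q: symmetrize with pi^(1/2) for a stable eigendecomposition
  sq <- sqrt(freq)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  decomp <- list(vals = eg$values,
                 left = eg$vectors / sq,          # D^-1/2 U
                 right = t(eg$vectors * sq))      # U' D^1/2
  structure(list(kind = kind, states = states, freq = freq, Q = Q,
                 decomp = decomp, alpha = alpha, p_inv = p_inv, k = as.integer(k),
                 rates = discrete_gamma_rates(alpha, k)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s, %d states, alpha=%g, p_inv=%g, K=%d\n",
              x$kind, length(x$states), x$alpha, x$p_inv, x$k))
  invisible(x)
}

#' Mean rates of K equal-probability discrete gamma categories
#'
#' Category rate = conditional mean of the gamma(shape, rate = shape)
#' distribution within each probability bin, so the category rates have
#' mean exactly one.
#'
#' @param alpha gamma shape (> 0)
#' @param k number of categories (>= 1)
#' @return numeric vector of length `k`
#' @export
discrete_gamma_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X ; a < X < b] for gamma(shape, rate) = (shape/rate) * diff of
  # pgamma(shape + 1) masses; times K for the conditional (bin prob 1/K)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [subst_model]
#' @param t branch length (non-negative, finite), in expected substitutions
#'   per site at rate one.
#' @return stochastic matrix over the model's states
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0",
                                   call. = FALSE)
  d <- model$decomp
  P <- d$left %*% (exp(d$vals * t) * d$right)
  P[P < 0] <- 0                      # clip eigendecomposition round-off
  dimnames(P) <- list(model$states, model$states)
  P
}

# Site-pattern log-likelihood of a pairwise count matrix at distance t.
# counts: n_states x n_states matrix of usable site-pair counts (x from seq a,
# y from seq b). Mixture: p_inv point mass at rate 0 plus K equal-weight
# gamma category rates.
pair_loglik <- function(counts, model, t) {
  n <- length(model$states)
  mix <- matrix(0, n, n)
  for (r in model$rates) {
    mix <- mix + transition_matrix(model, t * r) / model$k
  }
  lik <- (1 - model$p_inv) * model$freq * mix
  if (model$p_inv > 0) {
    diag(lik) <- diag(lik) + model$p_inv * model$freq
  }
  lik[lik < 1e-300] <- 1e-300
  sum(counts * log(lik))
}

# Encode an alignment into an integer matrix (rows = sequences); gaps and
# ambiguity codes become NA (missing).
encode_states <- function(a) {
  states <- core_states(a$alphabet)
  m <- aln_matrix(a)
  if (a$alphabet == "nucleotide") m[m == "U"] <- "T"
  out <- matrix(match(m, states), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

# Pairwise site-pattern counts with pairwise deletion of gaps/ambiguities.
pair_counts <- function(xi, yi, n_states) {
  ok <- !is.na(xi) & !is.na(yi)
  xi <- xi[ok]; yi <- yi[ok]
  if (!length(xi)) return(NULL)
  counts <- matrix(tabulate((yi - 1L) * n_states + xi, nbins = n_states^2),
                   n_states, n_states)
  counts
}

#' Maximum likelihood pairwise distance
#'
#' Maximizes the two-sequence likelihood over the evolutionary distance t
#' for a time-reversible model with discrete-gamma + invariant-sites rate
#' mixture. Sites where either sequence has a gap or ambiguity are excluded
#' (pairwise deletion). The optimum is located by Brent's method on
#' `[0, t_max]` to an absolute tolerance of 1e-8.
#'
#' @param a,b aligned sequences: character strings, or integer encodings as
#'   produced internally.
#' @param model a [subst_model]
#' @param t_max upper bound on the distance; an optimum at the bound marks
#'   the pair as saturated.
#' @return list with `distance`, `saturated` (logical), `n_sites` (usable
#'   sites), `loglik`.
#' @export
ml_pairwise_distance <- function(a, b, model, t_max = 10) {
  n <- length(model$states)
  if (is.character(a)) {
    al <- gene_alignment(c(s1 = a, s2 = b),
                         if (n == 4L) "nucleotide" else "amino-acid")
    enc <- encode_states(al)
    a <- enc[1, ]; b <- enc[2, ]
  }
  counts <- pair_counts(a, b, n)
  if (is.null(counts)) stop("no usable (ungapped, unambiguous) sites",
                            call. = FALSE)
  n_sites <- sum(counts)
  n_diff <- n_sites - sum(diag(counts))
  if (n_diff == 0L) {
    return(list(distance = 0, saturated = FALSE, n_sites = n_sites,
                loglik = pair_loglik(counts, model, 0)))
  }
  f <- function(t) -pair_loglik(counts, model, t)
  opt <- stats::optimize(f, interval = c(0, t_max), tol = 1e-8)
  t_hat <- opt$minimum
  # Brent never returns an exact endpoint; treat near-bound optima whose
  # likelihood is still improving at t_max as saturated
  saturated <- t_hat > t_max - 1e-4 && f(t_max) <= opt$objective + 1e-9
  list(distance = t_hat, saturated = saturated, n_sites = n_sites,
       loglik = -opt$objective)
}

#' All-pairs maximum likelihood distance matrix
#'
#' @param a a [gene_alignment]
#' @param model a [subst_model] matching the alignment alphabet
#' @param t_max passed to [ml_pairwise_distance]
#' @return a [pair_dist]; saturated or data-less pairs are masked, with the
#'   reasons in `attr(, "problems")` (data.frame pair/reason).
#' @export
ml_distance_matrix <- function(a, model, t_max = 10) {
  want <- if (model$kind == "JTT") "amino-acid" else "nucleotide"
  if (a$alphabet != want) {
    stop(sprintf("model %s expects a %s alignment", model$kind, want),
         call. = FALSE)
  }
  if (length(a) < 2L) stop("need >= 2 sequences", call. = FALSE)
  enc <- encode_states(a)
  nseq <- length(a$ids)
  vals <- matrix(0, nseq, nseq, dimnames = list(a$ids, a$ids))
  mask <- matrix(FALSE, nseq, nseq)
  probs <- list()
  for (i in seq_len(nseq - 1L)) {
    for (j in seq(i + 1L, nseq)) {
      res <- tryCatch(ml_pairwise_distance(enc[i, ], enc[j, ], model, t_max),
                      error = function(e) NULL)
      if (is.null(res)) {
        mask[i, j] <- mask[j, i] <- TRUE
        probs[[length(probs) + 1L]] <- data.frame(
          a = a$ids[i], b = a$ids[j], reason = "no-data")
      } else if (res$saturated) {
        mask[i, j] <- mask[j, i] <- TRUE
        probs[[length(probs) + 1L]] <- data.frame(
          a = a$ids[i], b = a$ids[j], reason = "saturated")
      } else {
        vals[i, j] <- vals[j, i] <- res$distance
      }
    }
  }
  d <- pair_dist(vals, mask)
  attr(d, "problems") <- if (length(probs)) do.call(rbind, probs) else
    data.frame(a = character(), b = character(), reason = character())
  d
}
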