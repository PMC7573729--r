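# Nei-Gojobori (1986) Dn/Ds: averaged synonymous/nonsynonymous site counts,
# equal-weight minimal-pathway difference counting, Jukes-Cantor correction.
# Standard genetic code only. Changes to/through stop codons are excluded
# from site denominators and pathway sets.

.kaks_cache <- new.env(parent = emptyenv())

#' Standard genetic code tables used by the Dn/Ds machinery
#'
#' @return list: `codons` (64), `aa` (named translation, `*` = stop),
#'   `sense` (61 sense codons), `syn_sites` (named synonymous site count per
#'   sense codon), `Sd`/`Nd` (61 x 61 pathway-averaged difference counts).
#' @export
codon_tables <- function() {
  if (!is.null(.kaks_cache$tab)) return(.kaks_cache$tab)
  nt <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1],
                  1L, paste, collapse = "")
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), character(1))
  sense <- codons[aa != "*"]
  syn_sites <- vapply(sense, function(cd) codon_syn_sites(cd, aa), numeric(1))
  m <- length(sense)
  Sd <- matrix(0, m, m, dimnames = list(sense, sense))
  Nd <- Sd
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j) {
        dn <- pathway_diffs(sense[i], sense[j], aa)
        Sd[i, j] <- Sd[j, i] <- dn[1]
        Nd[i, j] <- Nd[j, i] <- dn[2]
      }
    }
  }
  .kaks_cache$tab <- list(codons = codons, aa = aa, sense = sense,
                          syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .kaks_cache$tab
}

# synonymous site count of one sense codon: at each position, the fraction
# of non-stop single-nucleotide changes that are synonymous
codon_syn_sites <- function(cd, aa) {
  nt <- c("T", "C", "A", "G")
  ch <- strsplit(cd, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; legal <- 0L
    for (b in setdiff(nt, ch[pos])) {
      mut <- ch; mut[pos] <- b
      mcd <- paste(mut, collapse = "")
      if (aa[mcd] == "*") next
      legal <- legal + 1L
      if (aa[mcd] == aa[cd]) syn <- syn + 1L
    }
    if (legal > 0L) s <- s + syn / legal
  }
  s
}

# pathway-averaged (Sd, Nd) between two sense codons: enumerate all
# orderings of the differing positions, drop pathways passing through a stop
# codon, classify each step as synonymous or not, average with equal weight.
# If every pathway is blocked by stops, fall back to averaging over all.
pathway_diffs <- function(c1, c2, aa) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (!length(diffs)) return(c(0, 0))
  perms <- perm_list(diffs)
  tally <- function(skip_stops) {
    acc <- c(0, 0); used <- 0L
    for (ord in perms) {
      cur <- a; sd <- 0L; nd <- 0L; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        ncd <- paste(nxt, collapse = "")
        if (skip_stops && aa[ncd] == "*") { ok <- FALSE; break }
        if (aa[ncd] == aa[paste(cur, collapse = "")]) sd <- sd + 1L
        else nd <- nd + 1L
        cur <- nxt
      }
      if (ok) { acc <- acc + c(sd, nd); used <- used + 1L }
    }
    if (used) acc / used else NULL
  }
  out <- tally(TRUE)
  if (is.null(out)) out <- tally(FALSE)
  out
}

perm_list <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perm_list(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Extract comparable codon pairs from a codon alignment
#'
#' Codons containing a gap or ambiguity in either sequence, or translating
#' to a stop in either sequence, are excluded from Dn/Ds counting.
#'
#' @param a a [codon_alignment]
#' @param pair character vector of two sequence ids
#' @return data.frame with columns `position` (codon index), `codon_a`,
#'   `codon_b`; attribute `excluded` counts drops by reason.
#' @export
codon_filter <- function(a, pair) {
  stopifnot(inherits(a, "codon_alignment"), length(pair) == 2L,
            all(pair %in% a$ids))
  tab <- codon_tables()
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(a$seqs[[pair[1]]])
  cb <- split_codons(a$seqs[[pair[2]]])
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  stopish <- clean
  stopish[clean] <- tab$aa[ca[clean]] == "*" | tab$aa[cb[clean]] == "*"
  keep <- clean & !stopish
  if (!any(keep)) stop("no comparable codons for pair ",
                       paste(pair, collapse = "/"), call. = FALSE)
  out <- data.frame(position = which(keep), codon_a = ca[keep],
                    codon_b = cb[keep], stringsAsFactors = FALSE)
  attr(out, "excluded") <- c(gap_or_ambiguous = sum(!clean),
                             stop_codon = sum(stopish))
  out
}

#' Nei-Gojobori (1986) Dn/Ds for one pair of sequences
#'
#' Site counts are per-codon synonymous fractions summed over codons and
#' averaged across the two sequences; difference counts average Sd/Nd over
#' all minimal substitution pathways with equal weight (pathways through
#' stop codons excluded); proportions are Jukes-Cantor corrected,
#' `D = -(3/4) log(1 - (4/3) p)`. A result is `valid` when both Dn and Ds
#' are defined and `0 < omega < 9`.
#'
#' @param codons_a,codons_b equal-length character vectors of sense codons
#'   (as produced by [codon_filter]), or a data.frame from [codon_filter]
#'   passed as `codons_a`.
#' @return object of class `kaks_result`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ds`, `Dn`, `omega`, `valid`, `reason`, `n_codons`.
#' @export
ng86 <- function(codons_a, codons_b = NULL) {
  if (is.data.frame(codons_a)) {
    codons_b <- codons_a$codon_b
    codons_a <- codons_a$codon_a
  }
  stopifnot(length(codons_a) == length(codons_b), length(codons_a) >= 1L)
  tab <- codon_tables()
  if (!all(codons_a %in% tab$sense) || !all(codons_b %in% tab$sense)) {
    stop("non-sense codon passed to ng86; run codon_filter first",
         call. = FALSE)
  }
  nc <- length(codons_a)
  S <- (sum(tab$syn_sites[codons_a]) + sum(tab$syn_sites[codons_b])) / 2
  N <- 3 * nc - S
  idx <- cbind(match(codons_a, tab$sense), match(codons_b, tab$sense))
  Sd <- sum(tab$Sd[idx])
  Nd <- sum(tab$Nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ds <- jc(pS); Dn <- jc(pN)
  omega <- NA_real_; valid <- FALSE
  reason <- if (Sd + Nd == 0) {
    "identical"
  } else if (is.na(Ds) || is.na(Dn)) {
    "saturation"
  } else if (Ds == 0) {
    "zero-synonymous"
  } else {
    omega <- Dn / Ds
    if (omega <= 0) "zero-nonsynonymous"
    else if (omega >= 9) "omega-out-of-range"
    else { valid <- TRUE; "ok" }
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ds = Ds, Dn = Dn, omega = omega, valid = valid,
                 reason = reason, n_codons = nc),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> omega=%s (%s), Sd=%.3f/%.2f Nd=%.3f/%.2f over %d codons\n",
              ifelse(is.na(x$omega), "NA", sprintf("%.4f", x$omega)),
              x$reason, x$Sd, x$S, x$Nd, x$N, x$n_codons))
  invisible(x)
}

#' All-pairs Dn/Ds table and masked omega matrix
#'
#' Runs [codon_filter] + [ng86] on every unordered pair. Invalid pairs
#' (omega undefined or outside the open interval (0, 9)) are masked in the
#' returned matrix but retained in the table with their reason codes.
#'
#' @param a a [codon_alignment] with >= 2 sequences
#' @return list: `table` (one row per pair: gene_a, gene_b, S, N, Sd, Nd,
#'   pS, pN, Ds, Dn, omega, valid, reason) and `omega_dist` (a masked
#'   [pair_dist]).
#' @export
pairwise_kaks_table <- function(a) {
  stopifnot(inherits(a, "codon_alignment"))
  n <- length(a$ids)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  rows <- list()
  vals <- matrix(0, n, n, dimnames = list(a$ids, a$ids))
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      res <- tryCatch(ng86(codon_filter(a, c(a$ids[i], a$ids[j]))),
                      error = function(e) NULL)
      if (is.null(res)) {
        res <- list(S = NA, N = NA, Sd = NA, Nd = NA, pS = NA, pN = NA,
                    Ds = NA, Dn = NA, omega = NA, valid = FALSE,
                    reason = "no-data")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a$ids[i], gene_b = a$ids[j], S = res$S, N = res$N,
        Sd = res$Sd, Nd = res$Nd, pS = res$pS, pN = res$pN,
        Ds = res$Ds, Dn = res$Dn, omega = res$omega, valid = res$valid,
        reason = res$reason, stringsAsFactors = FALSE)
      if (res$valid) {
        vals[i, j] <- vals[j, i] <- res$omega
      } else {
        mask[i, j] <- mask[j, i] <- TRUE
      }
    }
  }
  list(table = do.call(rbind, rows), omega_dist = pair_dist(vals, mask))
}
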