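## Pairwise dN/dS under Nei-Gojobori (1986) counting with Jukes-Cantor
## correction, a codon-column bootstrap for selection classification, and a
## GY94-style codon simulator for calibration. Standard genetic code only
## (injectable for extension); ambiguity codes and gapped codon columns are
## dropped pairwise-complete.

codon_env <- new.env(parent = emptyenv())

standard_code <- function() {
  if (is.null(codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    codon_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  codon_env$code
}

sense_codons <- function(code = standard_code()) {
  names(code)[code != "*"]
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3", call. = FALSE)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

codon_resolved <- function(codon) {
  all(strsplit(codon, "")[[1]] %in% DNA_BASES)
}

## Per-codon expected synonymous site count: at each of the 3 positions,
## the fraction of the 3 possible single-base changes that preserve the
## amino acid. Changes creating a stop codon count as nonsynonymous, so
## every codon contributes exactly 3 sites (s + n = 3).
ng86_syn_sites <- function(codon, code = standard_code()) {
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      mut <- chars
      mut[p] <- b
      mut_codon <- paste(mut, collapse = "")
      if (code[[mut_codon]] == aa && code[[mut_codon]] != "*") s <- s + 1 / 3
    }
  }
  s
}

syn_sites_table <- function(code = standard_code()) {
  key <- paste0("sites_", substr(digest_code(code), 1, 8))
  if (is.null(codon_env[[key]])) {
    cods <- sense_codons(code)
    codon_env[[key]] <- stats::setNames(
      vapply(cods, ng86_syn_sites, numeric(1), code = code), cods)
  }
  codon_env[[key]]
}

digest_code <- function(code) paste(code, collapse = "")

perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

## Pathway-averaged (nonsyn, syn) differences between two codons: equal
## weight over all orderings of the differing positions, excluding
## orderings that pass through a stop codon (falling back to all orderings
## if every path hits a stop).
ng86_codon_diffs <- function(c1, c2, code = standard_code()) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  orderings <- perms[[as.character(length(diff_pos))]]
  tally <- function(skip_stops) {
    tot <- c(nd = 0, sd = 0)
    used <- 0L
    for (ord in orderings) {
      cur <- a
      path <- c(nd = 0, sd = 0)
      ok <- TRUE
      for (p in diff_pos[ord]) {
        nxt <- cur
        nxt[p] <- b[p]
        cod1 <- paste(cur, collapse = "")
        cod2 <- paste(nxt, collapse = "")
        if (skip_stops && code[[cod2]] == "*") { ok <- FALSE; break }
        if (code[[cod1]] == code[[cod2]]) path["sd"] <- path["sd"] + 1
        else path["nd"] <- path["nd"] + 1
        cur <- nxt
      }
      if (ok) { tot <- tot + path; used <- used + 1L }
    }
    if (used == 0L) return(NULL)
    tot / used
  }
  out <- tally(skip_stops = TRUE)
  if (is.null(out)) out <- tally(skip_stops = FALSE)
  out
}

#' Nei-Gojobori (1986) site and difference counts for an aligned pair
#'
#' Expected synonymous/nonsynonymous site counts are averaged over the two
#' sequences; observed differences are pathway-averaged with equal weight
#' over all minimal mutational orderings, excluding orderings through stop
#' codons. Codon columns containing a gap or ambiguity code in either
#' sequence are excluded whole; an internal stop codon in a resolved
#' column is a validation error naming the codon index.
#'
#' @param pair a `codon_pair` from [codon_pair()] or
#'   [simulate_codon_pair()].
#' @param code named codon -> amino acid table (default standard code).
#' @return list with `N`, `S`, `Nd`, `Sd`, `n_codons` (resolved columns)
#'   and per-codon vectors (`per_codon_n`, `per_codon_s`, `per_codon_nd`,
#'   `per_codon_sd`) for resampling.
#' @export
ng86_counts <- function(pair, code = standard_code()) {
  stopifnot(inherits(pair, "codon_pair"))
  ca <- split_codons(pair$seq_a)
  cb <- split_codons(pair$seq_b)
  resolved <- vapply(ca, codon_resolved, logical(1)) &
    vapply(cb, codon_resolved, logical(1))
  idx <- which(resolved)
  if (length(idx) == 0) stop("no fully resolved codon columns", call. = FALSE)
  stops <- idx[code[ca[idx]] == "*" | code[cb[idx]] == "*"]
  ## a final stop column is allowed and excluded from counting
  internal <- stops[stops < length(ca)]
  if (length(internal) > 0) {
    stop("internal stop codon at codon index ",
         paste(internal, collapse = ", "), call. = FALSE)
  }
  idx <- setdiff(idx, stops)
  if (length(idx) == 0) stop("no fully resolved codon columns", call. = FALSE)
  st <- syn_sites_table(code)
  s_per <- (st[ca[idx]] + st[cb[idx]]) / 2
  n_per <- 3 - s_per
  d <- vapply(idx, function(i) ng86_codon_diffs(ca[i], cb[i], code),
              c(nd = 0, sd = 0))
  list(N = sum(n_per), S = sum(s_per), Nd = sum(d["nd", ]),
       Sd = sum(d["sd", ]), n_codons = length(idx),
       per_codon_n = unname(n_per), per_codon_s = unname(s_per),
       per_codon_nd = unname(d["nd", ]), per_codon_sd = unname(d["sd", ]))
}

#' Construct an aligned codon-sequence pair
#'
#' @param seq_a,seq_b aligned coding sequences over `A/C/G/T/-` of equal
#'   length divisible by 3.
#' @param label_a,label_b sequence labels.
#' @return a `codon_pair`.
#' @export
codon_pair <- function(seq_a, seq_b, label_a = "a", label_b = "b") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 label_a = label_a, label_b = label_b),
            class = "codon_pair")
}

#' Read 2-sequence FASTA alignments as codon pairs
#'
#' @param path FASTA file with exactly two aligned sequences.
#' @return a `codon_pair`.
#' @export
read_codon_pair <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2) {
    stop("expected exactly 2 sequences in ", path, call. = FALSE)
  }
  codon_pair(as.character(seqs[[1]]), as.character(seqs[[2]]),
             names(seqs)[1], names(seqs)[2])
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(NA_real_)   # saturated
  -3 / 4 * log(arg)
}

#' Pairwise dN/dS with Jukes-Cantor correction
#'
#' Proportions `pN = Nd/N`, `pS = Sd/S` are corrected with
#' `d = -(3/4) log(1 - 4p/3)`; `omega = dN/dS`. Omega is undefined when
#' `dS` is zero; saturation (`p >= 3/4`) flags the result instead of
#' raising.
#'
#' @param pair a `codon_pair`.
#' @param code genetic-code table.
#' @return a `dnds_result`: the [ng86_counts()] fields plus `pN`, `pS`,
#'   `dN`, `dS`, `omega`, `saturated`, and `method` metadata recording the
#'   counting scheme.
#' @export
dnds <- function(pair, code = standard_code()) {
  cnt <- ng86_counts(pair, code)
  pN <- cnt$Nd / cnt$N
  pS <- cnt$Sd / cnt$S
  dN <- jc_correct(pN)
  dS <- jc_correct(pS)
  saturated <- (!is.na(pN) & pN >= 3 / 4) || (!is.na(pS) & pS >= 3 / 4)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(c(cnt, list(pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                        saturated = saturated,
                        method = "NG86 counting + JC69 correction (pairwise)")),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dnds_result> N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%s dS=%s omega=%s\n",
              x$N, x$S, x$Nd, x$Sd, format(x$dN, digits = 4),
              format(x$dS, digits = 4), format(x$omega, digits = 4)))
  invisible(x)
}

#' Classify selection from a dN/dS result
#'
#' Bootstraps codon columns to a percentile interval for omega. The gene
#' is called `neutral` when the interval covers 1 (exact equality of rates
#' being measure-zero), otherwise `positive`/`negative` by the sign of
#' `omega - 1`; `undefined` when omega itself is undefined. Bootstrap
#' replicates whose resampled dS is zero are dropped from the interval.
#'
#' @param result a `dnds_result`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param alpha interval level (default 0.05 for a 95% interval).
#' @param seed RNG seed for reproducibility.
#' @return list with `classification`, `omega`, `ci` (named lower/upper),
#'   `n_boot_used`.
#' @export
classify_selection <- function(result, n_boot = 1000L, alpha = 0.05,
                               seed = NULL) {
  stopifnot(inherits(result, "dnds_result"))
  if (is.na(result$omega)) {
    return(list(classification = "undefined", omega = NA_real_,
                ci = c(lower = NA_real_, upper = NA_real_),
                n_boot_used = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  nc <- result$n_codons
  om <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    N <- sum(result$per_codon_n[idx]); S <- sum(result$per_codon_s[idx])
    Nd <- sum(result$per_codon_nd[idx]); Sd <- sum(result$per_codon_sd[idx])
    dN <- jc_correct(Nd / N); dS <- jc_correct(Sd / S)
    om[b] <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  }
  om <- om[!is.na(om)]
  if (length(om) == 0) {
    return(list(classification = "undefined", omega = result$omega,
                ci = c(lower = NA_real_, upper = NA_real_),
                n_boot_used = 0L))
  }
  ci <- stats::quantile(om, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  classification <- if (ci[1] <= 1 && 1 <= ci[2]) "neutral"
                    else if (result$omega > 1) "positive" else "negative"
  list(classification = classification, omega = result$omega,
       ci = c(lower = ci[1], upper = ci[2]), n_boot_used = length(om))
}

## GY94-style 61-state rate matrix with uniform codon frequencies: rates
## between codons differing at one position, scaled by kappa for
## transitions and omega for nonsynonymous changes; normalised to one
## expected substitution per codon per unit branch length. Uniform
## frequencies make Q symmetric, so the transition matrix comes from a
## symmetric eigendecomposition.
gy94_rate_matrix <- function(omega, kappa, code = standard_code()) {
  cods <- sense_codons(code)
  k <- length(cods)
  chars <- do.call(rbind, strsplit(cods, ""))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  Q <- matrix(0, k, k, dimnames = list(cods, cods))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      diff <- which(chars[i, ] != chars[j, ])
      if (length(diff) != 1) next
      r <- 1
      if (is_transition(chars[i, diff], chars[j, diff])) r <- r * kappa
      if (code[[cods[i]]] != code[[cods[j]]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q / mean(-diag(Q))   # uniform frequencies: E[rate] is the plain mean
}

#' Simulate a codon-sequence pair at a planted omega
#'
#' Draws a uniform ancestor over the 61 sense codons and evolves two
#' lineages for branch length `t/2` each under a GY94-style codon model
#' with transition/transversion ratio `kappa`, nonsynonymous scaling
#' `omega`, uniform codon frequencies, and rates normalised to one
#' expected substitution per codon per unit `t`.
#'
#' @param omega planted dN/dS (>= 0).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param t total divergence in expected substitutions per codon.
#' @param n_codons number of codons.
#' @param seed RNG seed.
#' @return a `codon_pair` with attribute `truth` recording the
#'   parameters.
#' @export
simulate_codon_pair <- function(omega, kappa = 2, t, n_codons,
                                seed = NULL) {
  if (omega < 0 || t < 0 || n_codons < 1 || kappa <= 0) {
    stop("invalid simulation parameters", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cods <- sense_codons()
  anc <- sample(cods, n_codons, replace = TRUE)
  if (t == 0) {
    P <- diag(length(cods)); dimnames(P) <- list(cods, cods)
  } else {
    Q <- gy94_rate_matrix(omega, kappa)
    eig <- eigen(Q, symmetric = TRUE)
    P <- eig$vectors %*% diag(exp(eig$values * t / 2)) %*% t(eig$vectors)
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- list(cods, cods)
  }
  evolve <- function(x) {
    vapply(x, function(c0) sample(cods, 1, prob = P[c0, ]), character(1))
  }
  a <- evolve(anc)
  b <- evolve(anc)
  pair <- codon_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                     "lineage_a", "lineage_b")
  attr(pair, "truth") <- list(omega = omega, kappa = kappa, t = t,
                              n_codons = n_codons, seed = seed,
                              ancestor = paste(anc, collapse = ""))
  pair
}
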