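# Two-locus haplotype-frequency EM over the star alleles *1a, *1b, *5, *15,
# plus diplotype assignment with phase posteriors.

# P(genotype class i,j | f) under random mating, by summing f_h1 * f_h2 over
# all ordered haplotype pairs whose allele content gives dosages (i, j).
# Also used by the grid-search oracle in the tests.
#' Genotype-class probabilities implied by haplotype frequencies
#'
#' Returns the 3x3 matrix of probabilities of carrying i copies of 388G and
#' j copies of 521C under random mating of haplotypes with frequencies `f`.
#'
#' @param f numeric 4-vector of haplotype frequencies in the order
#'   *1a, *1b, *5, *15; must lie on the simplex.
#' @return 3x3 numeric matrix, rows = 388G dosage 0..2, cols = 521C dosage.
#' @export
genotype_class_probs <- function(f) {
  stopifnot(length(f) == 4L, all(f >= -1e-12), abs(sum(f) - 1) < 1e-6)
  f <- pmax(f, 0)
  g388 <- hap_carries_388G()
  g521 <- hap_carries_521C()
  P <- matrix(0, 3, 3, dimnames = list(g388 = 0:2, g521 = 0:2))
  for (h1 in 1:4) for (h2 in 1:4) {
    i <- g388[h1] + g388[h2]
    j <- g521[h1] + g521[h2]
    P[i + 1, j + 1] <- P[i + 1, j + 1] + f[h1] * f[h2]
  }
  P
}

# Unambiguous haplotype contributions: contrib[h, cell] = copies of haplotype
# h carried by a sample in genotype cell (i,j), for the 8 phase-determined
# cells. The double heterozygote (1,1) is handled in the E-step.
hap_contrib_matrix <- function() {
  contrib <- matrix(0L, nrow = 4, ncol = 9,
                    dimnames = list(hap_names(), NULL))
  # column index for cell (i, j) in the column-major flattening of the 3x3
  # count matrix (rows = 388G dosage i, cols = 521C dosage j)
  cell <- function(i, j) j * 3 + i + 1
  g388 <- hap_carries_388G()
  g521 <- hap_carries_521C()
  for (i in 0:2) for (j in 0:2) {
    if (i == 1 && j == 1) next
    # forced pair: distribute i copies of G and j copies of C over two
    # haplotypes; unique because at most one locus is heterozygous
    a388 <- c(i >= 1, i == 2)   # haplotype-wise G carriage
    a521 <- c(j >= 1, j == 2)
    for (k in 1:2) {
      h <- which(g388 == a388[k] & g521 == a521[k])
      contrib[h, cell(i, j)] <- contrib[h, cell(i, j)] + 1L
    }
  }
  contrib
}

em_loglik <- function(n, f) {
  P <- genotype_class_probs(f)
  sum(n[n > 0] * log(pmax(P[n > 0], .Machine$double.xmin)))
}

#' Estimate star-allele haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four haplotype frequencies
#' (*1a, *1b, *5, *15) from the 3x3 table of unphased two-locus genotype
#' classes, under random mating. Eight of the nine genotype classes determine
#' their haplotype pair; only the double heterozygote is phase-ambiguous, and
#' the E-step splits its count between the (*1a, *15) and (*1b, *5) phases in
#' proportion to their current probabilities. The M-step is gamete counting on
#' the expected haplotype counts. Marginal allele frequencies are preserved
#' exactly at every iterate.
#'
#' @param counts 3x3 matrix from [two_locus_counts()] (rows = 388G dosage,
#'   cols = 521C dosage).
#' @param init `"LE"` (default) starts from the product of observed allele
#'   frequencies (linkage-equilibrium start; deterministic), or a numeric
#'   4-vector on the simplex.
#' @param tol convergence tolerance on `max |delta f|` between iterations.
#' @param max_iter iteration cap.
#' @return A `haplotype_freqs` object: `f` (named 4-vector summing to 1),
#'   `loglik`, `n_iter`, `converged`, `identifiable` (FALSE when only the
#'   double-heterozygote class is observed, where the likelihood is flat along
#'   a ridge), `degenerate_split` (TRUE if any E-step hit a zero denominator
#'   and split 50/50), `loglik_trace` (per-iteration log-likelihood),
#'   `f_trace` (iterations x 4 matrix of frequency iterates) and `n`
#'   (samples used).
#' @examples
#' n <- matrix(0L, 3, 3); n[1, 1] <- 30L; n[3, 3] <- 10L
#' em_haplotype_frequencies(n)$f  # (0.75, 0, 0, 0.25)
#' @export
em_haplotype_frequencies <- function(counts, init = "LE", tol = 1e-10,
                                     max_iter = 10000L) {
  n <- counts
  stopifnot(is.matrix(n), all(dim(n) == c(3, 3)), all(n >= 0))
  N <- sum(n)
  if (N == 0) stop("empty genotype table", call. = FALSE)

  # observed marginal allele frequencies
  pG <- sum(n * matrix(0:2, 3, 3)) / (2 * N)          # rows index 388G dosage
  qC <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)

  if (identical(init, "LE")) {
    f <- c((1 - pG) * (1 - qC), pG * (1 - qC), (1 - pG) * qC, pG * qC)
  } else {
    stopifnot(is.numeric(init), length(init) == 4L, all(init >= 0),
              abs(sum(init) - 1) < 1e-9)
    f <- as.numeric(init)
  }

  identifiable <- (N - n[2, 2]) > 0 || n[2, 2] == 0
  contrib <- hap_contrib_matrix()
  n_vec <- as.numeric(n)
  degenerate <- FALSE
  trace <- numeric(0)
  f_trace <- list()
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    # E-step: expected haplotype counts
    H <- as.numeric(contrib %*% n_vec)
    n11 <- n[2, 2]
    if (n11 > 0) {
      den <- f[1] * f[4] + f[2] * f[3]
      w <- if (den > 0) (f[1] * f[4]) / den else {
        degenerate <- TRUE
        0.5
      }
      H <- H + n11 * c(w, 1 - w, 1 - w, w)
    }
    f_new <- H / (2 * N)
    trace[iter] <- em_loglik(n, f_new)
    f_trace[[iter]] <- f_new
    delta <- max(abs(f_new - f))
    f <- f_new
    if (n[2, 2] == 0) {
      # no phase-ambiguous class: the E-step is constant in f, so the first
      # M-step is already the maximum-likelihood gamete count
      converged <- TRUE
      break
    }
    if (!identifiable) {
      converged <- TRUE
      warning("only double-heterozygote samples observed: haplotype ",
              "frequencies are not identifiable (flat likelihood ridge)",
              call. = FALSE)
      break
    }
    if (delta < tol || iter >= max_iter) {
      converged <- delta < tol
      break
    }
  }

  structure(
    list(f = setNames(f, hap_names()), loglik = trace[iter],
         n_iter = iter, converged = converged, identifiable = identifiable,
         degenerate_split = degenerate, loglik_trace = trace,
         f_trace = do.call(rbind, f_trace), n = N),
    class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("<haplotype_freqs>", sprintf("%s=%.4f", names(x$f), x$f), "\n")
  cat(sprintf("  loglik %.4f after %d iteration(s); converged: %s%s\n",
              x$loglik, x$n_iter, x$converged,
              if (!x$identifiable) " (non-identifiable)" else ""))
  invisible(x)
}

#' Assign a star-allele diplotype to an unphased two-locus genotype
#'
#' Eight of the nine genotype classes force the haplotype pair. The double
#' heterozygote (one copy of 388G, one of 521C) is compatible with two
#' phases, *1a/*15 and *1b/*5; the more probable phase under the supplied
#' haplotype frequencies is reported, with its posterior probability
#' attached. Ties break toward *1a/*15.
#'
#' @param dosage_388,dosage_521 integers in 0..2 (no missing values; filter
#'   upstream).
#' @param f haplotype frequencies: a `haplotype_freqs` fit or a numeric
#'   4-vector (*1a, *1b, *5, *15). Only consulted for the double
#'   heterozygote.
#' @return A `diplotype` object: `alleles` (character pair of star names),
#'   `phase_posterior` in (0, 1], and `ambiguous` (TRUE only for the double
#'   heterozygote).
#' @export
assign_diplotype <- function(dosage_388, dosage_521, f = NULL) {
  if (is.na(dosage_388) || is.na(dosage_521))
    stop("missing dosage: exclude ungenotyped samples before diplotype ",
         "assignment", call. = FALSE)
  stopifnot(dosage_388 %in% 0:2, dosage_521 %in% 0:2)
  if (dosage_388 == 1 && dosage_521 == 1) {
    fv <- if (inherits(f, "haplotype_freqs")) f$f else f
    if (is.null(fv))
      stop("haplotype frequencies required for the double heterozygote",
           call. = FALSE)
    stopifnot(length(fv) == 4L)
    p_cis <- fv[1] * fv[4]    # *1a/*15
    p_trans <- fv[2] * fv[3]  # *1b/*5
    den <- p_cis + p_trans
    if (den == 0) {
      alleles <- c("*1a", "*15"); post <- 0.5
    } else if (p_cis >= p_trans) {
      alleles <- c("*1a", "*15"); post <- p_cis / den
    } else {
      alleles <- c("*1b", "*5"); post <- p_trans / den
    }
    return(structure(list(alleles = alleles,
                          phase_posterior = as.numeric(post),
                          ambiguous = TRUE),
                     class = "diplotype"))
  }
  a388 <- c(dosage_388 >= 1, dosage_388 == 2)
  a521 <- c(dosage_521 >= 1, dosage_521 == 2)
  alleles <- vapply(1:2, function(k)
    star_allele(if (a388[k]) "G" else "A", if (a521[k]) "C" else "T")$name,
    character(1))
  # canonical order: *1a, *1b, *5, *15
  alleles <- alleles[order(match(alleles, hap_names()))]
  structure(list(alleles = alleles, phase_posterior = 1, ambiguous = FALSE),
            class = "diplotype")
}

#' @export
print.diplotype <- function(x, ...) {
  cat(sprintf("<diplotype> %s/%s (phase posterior %.3f%s)\n",
              x$alleles[1], x$alleles[2], x$phase_posterior,
              if (x$ambiguous) ", phase-ambiguous" else ""))
  invisible(x)
}

#' Tabulate haplotype frequencies as percentages with expected counts
#'
#' @param fits named list of `haplotype_freqs` fits (typically "Total" plus
#'   one per group).
#' @param n_chromosomes named integer vector of chromosome counts, same
#'   names as `fits`.
#' @return data.frame: one row per star allele, per fit a percentage column
#'   (`pct_<name>`) and an EM-expected count column (`count_<name>`, real
#'   valued; rounding is display-only).
#' @export
haplotype_frequency_table <- function(fits, n_chromosomes) {
  stopifnot(length(fits) >= 1, all(names(fits) %in% names(n_chromosomes)))
  out <- data.frame(haplotype = hap_names(), stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]$f
    out[[paste0("pct_", nm)]] <- 100 * as.numeric(f)
    out[[paste0("count_", nm)]] <-
      as.numeric(f) * n_chromosomes[[nm]]
  }
  out
}
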