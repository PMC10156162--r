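# BLOSUM62-based string kernel over CDR3 amino-acid sequences.
#
# The raw kernel K(s, t) sums, over every k >= 1 and every pair of k-mers
# (contiguous substrings, one from each sequence), the product over aligned
# positions of a substitution-derived amino-acid similarity
# m(a, b) = exp(beta * (BLOSUM62[a, b] - max(BLOSUM62))), which lies in
# (0, 1]. The reported score is the normalized K(s, t) / sqrt(K(s,s) K(t,t)),
# so identical sequences score exactly 1.

.kernel_cache <- new.env(parent = emptyenv())

aa_similarity_matrix <- function(beta = 0.11387) {
  key <- paste0("S", beta)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  b <- e$BLOSUM62[aa, aa]
  s <- exp(beta * (b - max(b)))
  .kernel_cache[[key]] <- s
  s
}

# Raw (unnormalized) kernel via the suffix-product recursion
# D[i, j] = m(s_i, t_j) * (1 + D[i+1, j+1]); K = sum_ij D[i, j].
# Computed diagonal-wise with cumulative products.
kernel_raw <- function(si, ti, S) {
  n1 <- length(si); n2 <- length(ti)
  total <- 0
  for (d in (-(n1 - 1)):(n2 - 1)) {
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    len <- min(n1 - i0, n2 - j0) + 1L
    m <- S[cbind(si[i0:(i0 + len - 1L)], ti[j0:(j0 + len - 1L)])]
    cp <- cumprod(m)
    total <- total + sum(rev(cumsum(rev(cp))) / c(1, cp[-len]))
  }
  total
}

#' Normalized string-kernel similarity between two CDR3 sequences
#'
#' A BLOSUM62-derived k-mer kernel over amino-acid strings of possibly
#' different lengths, normalized so identical sequences score 1. See the
#' methods vignette for the construction. No flank trimming is applied by
#' default; `trim_flanks = TRUE` removes the first and last residue of each
#' sequence before scoring.
#'
#' @param cdr3_a,cdr3_b Non-empty amino-acid strings (vectorized;
#'   recycled to a common length).
#' @param beta Exponential scaling of the substitution matrix
#'   (default 0.11387).
#' @param trim_flanks Remove the first and last residue first.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
cdr3_kernel_similarity <- function(cdr3_a, cdr3_b, beta = 0.11387,
                                   trim_flanks = FALSE) {
  S <- aa_similarity_matrix(beta)
  aa <- rownames(S)
  n <- max(length(cdr3_a), length(cdr3_b))
  cdr3_a <- rep_len(cdr3_a, n)
  cdr3_b <- rep_len(cdr3_b, n)
  vapply(seq_len(n), function(i) {
    s <- encode_cdr3(cdr3_a[i], aa, trim_flanks)
    t <- encode_cdr3(cdr3_b[i], aa, trim_flanks)
    kst <- kernel_raw(s, t, S)
    kst / sqrt(kernel_raw(s, s, S) * kernel_raw(t, t, S))
  }, numeric(1))
}

encode_cdr3 <- function(x, aa, trim_flanks) {
  if (is.na(x) || !nzchar(x)) {
    stop("CDR3 sequence must be a non-empty string", call. = FALSE)
  }
  if (trim_flanks) {
    if (nchar(x) < 3) stop("CDR3 too short to trim flanks: '", x, "'",
                           call. = FALSE)
    x <- substr(x, 2, nchar(x) - 1)
  }
  idx <- match(strsplit(x, "")[[1]], aa)
  if (anyNA(idx)) {
    stop("non-amino-acid character in CDR3 '", x, "'", call. = FALSE)
  }
  idx
}

#' Single specificity label per clonotype
#'
#' Restricts to clonotypes carrying both chains and labels each with its
#' expected target pMHC or, when no expected target exists, with its
#' highest-concordance pMHC (ties broken toward more supporting GEMs, then
#' lexicographically). Cross-reactive overlap is thereby avoided: a
#' clonotype contributes to exactly one specificity.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param expected Expected binders from [expected_binders()].
#' @return Tibble `clonotype_id`, `pmhc_id` (the label), `cdr3a`, `cdr3b`.
#' @export
clonotype_specificity_labels <- function(ds, expected) {
  conc <- binding_concordance(ds)
  best_conc <- conc |>
    arrange(.data$clonotype_id, dplyr::desc(.data$fraction),
            dplyr::desc(.data$n_support), .data$pmhc_id) |>
    group_by(.data$clonotype_id) |>
    slice(1) |>
    ungroup() |>
    select(all_of(c("clonotype_id", "pmhc_id")))
  ct <- ds$clonotypes |>
    filter(!is.na(.data$cdr3a), !is.na(.data$cdr3b)) |>
    select(all_of(c("clonotype_id", "cdr3a", "cdr3b")))
  exp_lab <- expected$pmhc_id[match(ct$clonotype_id, expected$clonotype_id)]
  conc_lab <- best_conc$pmhc_id[match(ct$clonotype_id,
                                      best_conc$clonotype_id)]
  ct$pmhc_id <- ifelse(is.na(exp_lab), conc_lab, exp_lab)
  filter(ct, !is.na(.data$pmhc_id))
}

#' Intra- and inter-specificity similarity scores per clonotype
#'
#' For each labeled both-chain clonotype: the intra-score is its maximum
#' summed alpha+beta kernel similarity to all other clonotypes sharing its
#' pMHC label; the inter-score is the maximum over a seeded random sample
#' (without replacement, of the same size as the intra comparison set) of
#' clonotypes with other labels. Clonotypes with no same-label partner are
#' excluded. Computation is peptide-wise: the same clonotype is an intra
#' partner for its own label and an inter candidate for every other.
#'
#' @param labels Tibble from [clonotype_specificity_labels()].
#' @param seed Seed for the inter-set sampling.
#' @param beta,trim_flanks Passed to the kernel.
#' @return Tibble `clonotype_id`, `pmhc_id`, `intra_score`, `inter_score`,
#'   `n_intra_partners`, `n_inter_partners` (scores in `[0, 2]`).
#' @export
intra_inter_scores <- function(labels, seed = 1L, beta = 0.11387,
                               trim_flanks = FALSE) {
  n <- nrow(labels)
  if (n < 2L) {
    warning("fewer than 2 labeled clonotypes; no similarity records",
            call. = FALSE)
    return(tibble(clonotype_id = character(), pmhc_id = character(),
                  intra_score = numeric(), inter_score = numeric(),
                  n_intra_partners = integer(),
                  n_inter_partners = integer()))
  }
  sim <- pairwise_summed_similarity(labels$cdr3a, labels$cdr3b, beta,
                                    trim_flanks)
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    same <- which(labels$pmhc_id == labels$pmhc_id[i])
    same <- setdiff(same, i)
    if (!length(same)) next
    other <- which(labels$pmhc_id != labels$pmhc_id[i])
    if (!length(other)) next
    m <- length(same)
    pick <- if (length(other) <= m) other else sample(other, m)
    rows[[i]] <- tibble(
      clonotype_id = labels$clonotype_id[i],
      pmhc_id = labels$pmhc_id[i],
      intra_score = max(sim[i, same]),
      inter_score = max(sim[i, pick]),
      n_intra_partners = m,
      n_inter_partners = length(pick)
    )
  }
  bind_rows(rows)
}

# Symmetric matrix of summed alpha+beta normalized kernel similarities.
pairwise_summed_similarity <- function(cdr3a, cdr3b, beta = 0.11387,
                                       trim_flanks = FALSE) {
  S <- aa_similarity_matrix(beta)
  aa <- rownames(S)
  chain_matrix <- function(seqs) {
    uniq <- unique(seqs)
    enc <- lapply(uniq, encode_cdr3, aa = aa, trim_flanks = trim_flanks)
    selfk <- vapply(enc, function(e) kernel_raw(e, e, S), numeric(1))
    nu <- length(uniq)
    m <- diag(1, nu)
    if (nu > 1) {
      for (i in seq_len(nu - 1)) {
        for (j in (i + 1):nu) {
          v <- kernel_raw(enc[[i]], enc[[j]], S) / sqrt(selfk[i] * selfk[j])
          m[i, j] <- v
          m[j, i] <- v
        }
      }
    }
    idx <- match(seqs, uniq)
    m[idx, idx, drop = FALSE]
  }
  chain_matrix(cdr3a) + chain_matrix(cdr3b)
}

#' ROC-AUC separating intra- from inter-specificity similarity scores
#'
#' Intra-specificity comparisons are regarded as true positives and
#' inter-specificity comparisons as true negatives; the AUC is the rank
#' statistic P(random intra score > random inter score), ties counted half.
#'
#' @param records Tibble from [intra_inter_scores()], or a list with
#'   numeric elements `intra` and `inter`.
#' @return AUC in `[0, 1]` (`NA` with a warning when a class is empty).
#' @export
similarity_auc <- function(records) {
  if (is.data.frame(records)) {
    intra <- records$intra_score
    inter <- records$inter_score
  } else {
    intra <- records$intra
    inter <- records$inter
  }
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (!length(intra) || !length(inter)) {
    warning("need at least one intra and one inter score; AUC undefined",
            call. = FALSE)
    return(NA_real_)
  }
  r <- rank(c(intra, inter))
  n1 <- length(intra)
  n2 <- length(inter)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Test whether intra-similarity exceeds inter-similarity
#'
#' One-sided paired Wilcoxon signed-rank test over the per-clonotype
#' (intra - inter) differences.
#'
#' @param records Tibble from [intra_inter_scores()].
#' @return The one-sided p-value (`NA` with a warning when every difference
#'   is zero).
#' @export
intra_vs_inter_test <- function(records) {
  res <- signed_rank_test(records$intra_score, records$inter_score,
                          alternative = "greater")
  if (is.na(res$p_value)) {
    warning("all intra/inter differences are zero; test undefined",
            call. = FALSE)
  }
  res$p_value
}
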