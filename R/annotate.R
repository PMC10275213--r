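# Mapping classes to categorical biomarkers and quantifying dependence
# between classification schemes.

# Pairwise-complete labels: neurons missing (NA) in either scheme are
# dropped, mirroring the "classified by both" convention.
paired_labels <- function(x, y) {
  if (length(x) != length(y))
    stopf("labelings must cover the same neurons")
  keep <- !is.na(x) & !is.na(y)
  list(x = as.character(x[keep]), y = as.character(y[keep]))
}

#' Empirical posterior probability table p(Y = j | X = i)
#'
#' @param x,y Two categorical labelings of the same neurons (`NA` =
#'   unclassified; such neurons are dropped pairwise).
#' @return Matrix of conditional probabilities; rows (classes of `x`)
#'   sum to 1.
#' @export
posterior_table <- function(x, y) {
  p <- paired_labels(x, y)
  if (!length(p$x)) stopf("no neurons classified by both schemes")
  tab <- table(p$x, p$y)
  sweep(unclass(tab), 1L, rowSums(tab), "/")
}

#' Dominant-category label per class
#'
#' Class `i` receives label `j` iff `p(Y = j | X = i) > threshold`
#' (strict inequality); otherwise it stays unlabeled (`NA`).
#'
#' @param posteriors Table from [posterior_table()].
#' @param threshold Posterior threshold; the conventional value is 0.67.
#' @return Named character vector, one entry per class, `NA` where no
#'   category dominates.
#' @export
dominant_label <- function(posteriors, threshold = 0.67) {
  out <- apply(posteriors, 1L, function(row) {
    j <- which.max(row)
    if (row[j] > threshold) colnames(posteriors)[j] else NA_character_
  })
  names(out) <- rownames(posteriors)
  out
}

#' Shannon entropy of a categorical labeling (bits)
#'
#' @param x Categorical labeling (`NA` dropped).
#' @return Entropy in bits (base-2 logs throughout the package).
#' @export
label_entropy <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("no labeled neurons")
  p <- as.numeric(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two labelings (bits)
#'
#' @inheritParams posterior_table
#' @return `I(X; Y) >= 0` in bits, computed from the empirical joint
#'   distribution over pairwise-complete neurons.
#' @export
mutual_information <- function(x, y) {
  p <- paired_labels(x, y)
  if (!length(p$x)) stopf("no neurons classified by both schemes")
  joint <- table(p$x, p$y) / length(p$x)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Directional normalized mutual information NMI(X -> Y)
#'
#' `NMI(X -> Y) = I(X; Y) / H(Y)`: the proportion of the uncertainty in
#' `Y` explained by `X`. Equals 1 when the labelings are identical (up to
#' renaming) and 0 when independent. When `Y` is constant (`H(Y) = 0`)
#' the ratio is undefined: the function returns 1 if `X` is also
#' constant, else 0, with attribute `degenerate = TRUE`.
#'
#' @inheritParams posterior_table
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  p <- paired_labels(x, y)
  hy <- label_entropy(p$y)
  if (hy == 0) {
    out <- if (label_entropy(p$x) == 0) 1 else 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mutual_information(p$x, p$y) / hy
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-adjusted agreement between two partitions of the
#' same neurons, restricted to neurons classified by both (pairwise
#' `NA` removal). 1 for identical partitions; expected value 0 for
#' independent ones. Symmetric and invariant to label renaming.
#'
#' @inheritParams posterior_table
#' @return The ARI (a single number, possibly negative).
#' @export
adjusted_rand_index <- function(x, y) {
  p <- paired_labels(x, y)
  n <- length(p$x)
  if (n < 2) stopf("need at least 2 neurons classified by both schemes")
  tab <- table(p$x, p$y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.numeric(tab))
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Mean absolute difference between two probability distributions
#'
#' @param dist_a,dist_b Named probability vectors over the same
#'   categories (order-insensitive).
#' @return Mean of `|a_c - b_c|` across categories.
#' @export
mean_absolute_difference <- function(dist_a, dist_b) {
  if (is.null(names(dist_a)) || is.null(names(dist_b))) {
    if (length(dist_a) != length(dist_b))
      stopf("distributions must cover the same categories")
  } else {
    if (!setequal(names(dist_a), names(dist_b)))
      stopf("distributions must cover the same categories")
    dist_b <- dist_b[names(dist_a)]
  }
  mean(abs(dist_a - dist_b))
}

#' Pairwise NMI matrix across several classification schemes
#'
#' @param schemes Named list of categorical labelings over the same
#'   neurons.
#' @return Matrix `M` with `M[i, j] = NMI(scheme_i -> scheme_j)`.
#' @export
nmi_matrix <- function(schemes) {
  k <- length(schemes)
  out <- matrix(NA_real_, k, k,
                dimnames = list(names(schemes), names(schemes)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      out[i, j] <- as.numeric(nmi(schemes[[i]], schemes[[j]]))
  out
}
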