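#' Filter contigs by length
#'
#' Strict length filter used before binning: contigs are kept only when
#' longer than `min_len_bp` (a 2,000 bp contig is excluded at the default).
#'
#' @param cs A [contig_set()].
#' @param min_len_bp Strict lower bound in bp (default 2000).
#' @return The filtered `contig_set`.
#' @export
filter_contigs <- function(cs, min_len_bp = 2000) {
  stopifnot(inherits(cs, "contig_set"))
  out <- cs[cs$length > min_len_bp, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(cs))
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator
#' and denominator. Returns 0 for a sequence with no A/C/G/T base.
#'
#' @param sequence A/C/G/T/N string.
#' @return GC fraction in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGC")  # 0.5
gc_content <- function(sequence) {
  counts <- table(strsplit(toupper(sequence), "")[[1]])
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  acgt <- sum(counts[c("A", "C", "G", "T")], na.rm = TRUE)
  if (acgt == 0) return(0)
  gc / acgt
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# All canonical k-mers (lexicographic min of k-mer and reverse complement),
# sorted; 136 of them for k = 4.
canonical_kmers <- function(k) {
  all <- do.call(paste0, expand.grid(rep(list(BASES), k),
                                     stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  sort(unique(pmin(all, revcomp(all))))
}

# Canonical k-mer multiset of one sequence; windows containing N (or any
# non-ACGT character) are skipped.
sequence_kmers <- function(sequence, k) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k")
  starts <- seq_len(L - k + 1)
  fwd <- substring(sequence, starts, starts + k - 1)
  valid <- !grepl("[^ACGT]", fwd)
  fwd <- fwd[valid]
  if (length(fwd) == 0) return(character(0))
  rc_seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "")[[1]]),
                  collapse = "")
  rc_all <- substring(rc_seq, starts, starts + k - 1)
  # window i of the forward strand is window (n_windows - i + 1) of the
  # reverse complement, read in reverse order
  rc <- rev(rc_all)[valid]
  pmin(fwd, rc)
}

#' Canonical k-mer frequency vector
#'
#' Counts every k-length window of the sequence, maps each k-mer to the
#' lexicographic minimum of itself and its reverse complement (strand
#' insensitivity), skips windows containing `N`, and normalizes to sum 1.
#' For k = 4 the feature space has exactly 136 canonical tetranucleotides.
#'
#' @param sequence A/C/G/T/N string with at least one valid window.
#' @param k k-mer size (default 4).
#' @param canonical Collapse reverse complements (default `TRUE`).
#' @return Named numeric vector over all (canonical) k-mers, summing to 1.
#' @export
#' @examples
#' kmer_frequencies("ACGTACGT")  # ACGT 0.4, CGTA 0.4, GTAC 0.2
kmer_frequencies <- function(sequence, k = 4, canonical = TRUE) {
  kmers <- if (canonical) sequence_kmers(sequence, k)
  else {
    sequence <- toupper(sequence)
    starts <- seq_len(nchar(sequence) - k + 1)
    w <- substring(sequence, starts, starts + k - 1)
    w[!grepl("[^ACGT]", w)]
  }
  if (length(kmers) == 0)
    stop("no valid k-mer window (sequence too short or all windows contain N)")
  universe <- if (canonical) canonical_kmers(k)
  else sort(do.call(paste0, expand.grid(rep(list(BASES), k),
                                        stringsAsFactors = FALSE)[, k:1,
                                                                  drop = FALSE]))
  counts <- table(factor(kmers, levels = universe))
  freqs <- as.numeric(counts) / length(kmers)
  names(freqs) <- universe
  freqs
}

#' Canonical tetranucleotide feature matrix
#'
#' One row per contig, one column per canonical 4-mer (136 columns for
#' k = 4); rows sum to 1.
#'
#' @param cs A [contig_set()].
#' @param k k-mer size.
#' @return Numeric matrix with contig ids as row names.
#' @export
feature_matrix <- function(cs, k = 4) {
  stopifnot(inherits(cs, "contig_set"))
  m <- t(vapply(cs$sequence, kmer_frequencies, numeric(length(canonical_kmers(k))),
                k = k, USE.NAMES = FALSE))
  rownames(m) <- cs$contig_id
  m
}

#' 2-D embedding of contig k-mer features
#'
#' `"pca"` projects onto the first two principal components and is fully
#' deterministic; `"tsne"` runs an exact (non-approximated) t-SNE with a
#' fixed seed, matching how binned contigs are conventionally visualized.
#' Clustering never depends on the embedding; it is for visualization.
#'
#' @param fm Feature matrix from [feature_matrix()].
#' @param method `"pca"` or `"tsne"`.
#' @param perplexity t-SNE perplexity (requires at least
#'   `3 * perplexity + 1` contigs).
#' @param seed t-SNE seed (default 0); identical seeds give identical
#'   coordinates.
#' @param n_components Number of output dimensions (2).
#' @return data.frame with columns `contig_id`, `x`, `y`.
#' @export
embed_contigs <- function(fm, method = c("pca", "tsne"), perplexity = 30,
                          seed = 0, n_components = 2) {
  method <- match.arg(method)
  if (method == "pca") {
    p <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(p$x))
    xy <- p$x[, seq_len(k), drop = FALSE]
    if (k < n_components)
      xy <- cbind(xy, matrix(0, nrow(xy), n_components - k))
  } else {
    if (nrow(fm) < max(5, 3 * perplexity + 1))
      stop("too few contigs for perplexity ", perplexity,
           "; need at least ", max(5, 3 * perplexity + 1))
    xy <- tsne_exact(fm, perplexity = perplexity, seed = seed,
                     n_components = n_components)
  }
  data.frame(contig_id = rownames(fm), x = xy[, 1], y = xy[, 2],
             row.names = NULL)
}

#' Cluster contigs into genome bins
#'
#' Default is density-based clustering (DBSCAN) on the raw 136-dimensional
#' canonical 4-mer frequencies, so binning is reproducible and independent
#' of t-SNE randomness; `eps` defaults to a k-distance heuristic (2x the
#' median distance to the `min_samples`-th nearest neighbour). k-means on
#' the features is available as the alternative. Per-bin GC is the
#' length-weighted mean of member GC; when truth labels are present,
#' purity is computed per bin as the largest fraction of member bp from
#' one source genome, and overall as the bp-weighted mean over non-noise
#' bins.
#'
#' @param fm Feature matrix from [feature_matrix()].
#' @param cs The matching [contig_set()] (lengths, GC, truth labels).
#' @param method `"dbscan"` or `"kmeans"`.
#' @param eps DBSCAN radius; `NULL` for the k-distance heuristic.
#' @param min_samples DBSCAN core-point neighbourhood size.
#' @param k Number of clusters for k-means.
#' @param seed k-means seed.
#' @return An object of class `bin_assignment`: data.frame `contig_id`,
#'   `bin_id` (-1 = noise, DBSCAN only), `length`, `gc`, with attributes
#'   `bins` (per-bin n_contigs, total_bp, gc, purity) and `purity`
#'   (overall).
#' @export
cluster_bins <- function(fm, cs, method = c("dbscan", "kmeans"), eps = NULL,
                         min_samples = 5, k = 2, seed = 0) {
  method <- match.arg(method)
  stopifnot(inherits(cs, "contig_set"), nrow(fm) == nrow(cs),
            all(rownames(fm) == cs$contig_id))
  if (method == "dbscan") {
    d <- as.matrix(stats::dist(fm))
    if (is.null(eps)) {
      kd <- apply(d, 1, function(r) sort(r)[min(min_samples + 1, ncol(d))])
      eps <- 2 * stats::median(kd)
    }
    bin_id <- dbscan_impl(d, eps = eps, min_pts = min_samples)
  } else {
    km <- with_seed(seed, stats::kmeans(fm, centers = k, nstart = 10))
    bin_id <- km$cluster
  }
  out <- data.frame(contig_id = cs$contig_id, bin_id = bin_id,
                    length = cs$length, gc = cs$gc)
  truth <- cs$genome
  ids <- sort(unique(bin_id[bin_id != -1]))
  bins <- do.call(rbind, lapply(ids, function(b) {
    sel <- bin_id == b
    pur <- if (!is.null(truth)) {
      bp <- tapply(cs$length[sel], truth[sel], sum)
      max(bp) / sum(bp)
    } else NA_real_
    data.frame(bin_id = b, n_contigs = sum(sel),
               total_bp = sum(cs$length[sel]),
               gc = sum(cs$gc[sel] * cs$length[sel]) / sum(cs$length[sel]),
               purity = pur)
  }))
  overall <- if (!is.null(truth) && length(ids) > 0)
    sum(bins$purity * bins$total_bp) / sum(bins$total_bp) else NA_real_
  structure(out, bins = bins, purity = overall, eps = if (method == "dbscan") eps,
            class = c("bin_assignment", "data.frame"))
}

#' @export
print.bin_assignment <- function(x, ...) {
  bins <- attr(x, "bins")
  n_noise <- sum(x$bin_id == -1)
  cat(sprintf("<bin_assignment> %d contigs in %d bin(s)%s\n", nrow(x),
              if (is.null(bins)) 0 else nrow(bins),
              if (n_noise) sprintf(" (+%d noise)", n_noise) else ""))
  if (!is.null(bins)) print.data.frame(bins, digits = 4, row.names = FALSE)
  if (!is.na(attr(x, "purity")))
    cat(sprintf("  overall purity (bp-weighted): %.3f\n", attr(x, "purity")))
  invisible(x)
}

#' k-mer containment of one assembly in another
#'
#' Fraction of the canonical k-mer set of `b` that also occurs in `a`:
#' `|kmers(b) n kmers(a)| / |kmers(b)|`. An approximation to alignment-based
#' genome overlap; with k = 21, random collisions are negligible.
#'
#' @param a,b [contig_set()] objects (reference and query).
#' @param k k-mer size (default 21).
#' @return Containment fraction in \[0, 1\].
#' @export
kmer_containment <- function(a, b, k = 21) {
  stopifnot(inherits(a, "contig_set"), inherits(b, "contig_set"))
  set_of <- function(cs) {
    kl <- lapply(cs$sequence[nchar(cs$sequence) >= k], sequence_kmers, k = k)
    unique(unlist(kl))
  }
  sb <- set_of(b)
  if (length(sb) == 0) stop("no valid k-mers in `b`")
  sa <- set_of(a)
  sum(sb %in% sa) / length(sb)
}
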