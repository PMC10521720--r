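#' Genome specification for contig simulation
#'
#' Truth model for the binning stage: each genome is a Markov chain over
#' A/C/G/T whose stationary composition matches the requested GC fraction.
#' Order 0 draws bases i.i.d.; order 1 adds a genome-specific random
#' dinucleotide signature (each genome gets its own transition matrix,
#' tilted so that the stationary GC equals `gc`), which gives genomes with
#' similar GC distinct tetranucleotide profiles.
#'
#' @param name Genome name.
#' @param gc GC fraction, strictly inside (0, 1).
#' @param markov_order 0 or 1.
#' @param n_contigs Number of contigs (>= 1).
#' @param min_bp,max_bp Contig length range in bp (min_bp >= 1).
#' @param length_dist `"uniform"` or `"loguniform"`.
#' @param signature_strength For order 1: sd of the random log-perturbation
#'   of transition probabilities.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(name, gc = 0.5, markov_order = 0, n_contigs = 20,
                        min_bp = 5000, max_bp = 10000,
                        length_dist = c("uniform", "loguniform"),
                        signature_strength = 0.3) {
  if (!(gc > 0 && gc < 1)) stop("`gc` must be strictly inside (0, 1)")
  if (!markov_order %in% c(0, 1)) stop("`markov_order` must be 0 or 1")
  if (n_contigs < 1) stop("`n_contigs` must be >= 1")
  if (min_bp < 1 || max_bp < min_bp) stop("invalid contig length range")
  structure(list(name = name, gc = gc, markov_order = markov_order,
                 n_contigs = n_contigs, min_bp = min_bp, max_bp = max_bp,
                 length_dist = match.arg(length_dist),
                 signature_strength = signature_strength),
            class = "genome_spec")
}

BASES <- c("A", "C", "G", "T")

# Stationary distribution of a 4x4 transition matrix.
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

# Tilt a random positive matrix Q into a stochastic matrix whose stationary
# GC equals the target: P_ij proportional to Q_ij * w_j with w favoring
# G/C by a factor found by 1-D root search.
tilted_transition <- function(Q, gc_target) {
  gc_of <- function(theta) {
    w <- c(1 - theta, theta, theta, 1 - theta)
    P <- sweep(Q, 2, w, `*`)
    P <- P / rowSums(P)
    pi <- stationary_dist(P)
    sum(pi[c(2, 3)])
  }
  theta <- stats::uniroot(function(t) gc_of(t) - gc_target,
                          interval = c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  w <- c(1 - theta, theta, theta, 1 - theta)
  P <- sweep(Q, 2, w, `*`)
  P / rowSums(P)
}

# Sample one sequence of length L from a first-order chain (integer states).
sample_markov1 <- function(L, P, pi0) {
  cum <- t(apply(P, 1, cumsum))
  s <- integer(L)
  s[1] <- sample.int(4, 1, prob = pi0)
  u <- stats::runif(L)
  for (i in 2:L) s[i] <- findInterval(u[i], cum[s[i - 1], ]) + 1L
  s
}

#' Simulate multi-genome contig sets
#'
#' Draws contigs from per-genome (order 0 or 1) Markov chains whose
#' stationary base composition matches each genome's requested GC, with
#' the source genome kept as a truth label for purity evaluation.
#'
#' @param specs A [genome_spec()] or list of them.
#' @param seed Integer seed; fixed seeds give bit-identical contig sets.
#' @return An object of class `contig_set`: a data.frame with columns
#'   `contig_id`, `sequence`, `length`, `gc`, `genome` (truth label).
#' @export
#' @examples
#' cs <- simulate_contigs(list(
#'   genome_spec("sar11", gc = 0.293, n_contigs = 5, min_bp = 2000, max_bp = 4000),
#'   genome_spec("alto", gc = 0.60, n_contigs = 5, min_bp = 2000, max_bp = 4000)),
#'   seed = 1)
#' cs
simulate_contigs <- function(specs, seed = NULL) {
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  seeds <- derive_seeds(seed, length(specs))
  recs <- lapply(seq_along(specs), function(g) {
    sp <- specs[[g]]
    with_seed(seeds[[g]], {
      L <- if (sp$length_dist == "uniform")
        round(stats::runif(sp$n_contigs, sp$min_bp, sp$max_bp))
      else round(exp(stats::runif(sp$n_contigs, log(sp$min_bp), log(sp$max_bp))))
      p0 <- c((1 - sp$gc) / 2, sp$gc / 2, sp$gc / 2, (1 - sp$gc) / 2)
      P <- NULL
      if (sp$markov_order == 1) {
        Q <- matrix(exp(stats::rnorm(16, 0, sp$signature_strength)), 4, 4)
        P <- tilted_transition(Q, sp$gc)
        pi0 <- stationary_dist(P)
      }
      seqs <- vapply(L, function(l) {
        states <- if (sp$markov_order == 0)
          sample.int(4, l, replace = TRUE, prob = p0)
        else sample_markov1(l, P, pi0)
        paste(BASES[states], collapse = "")
      }, character(1))
      data.frame(
        contig_id = sprintf("%s_contig_%03d", sp$name, seq_len(sp$n_contigs)),
        sequence = seqs, length = as.integer(L),
        gc = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE),
        genome = sp$name)
    })
  })
  contig_set(do.call(rbind, recs))
}

#' Construct a contig set
#'
#' @param records data.frame with at least `contig_id` and `sequence`
#'   (A/C/G/T/N strings); `length`, `gc` are recomputed if absent,
#'   `genome` (truth label) is optional.
#' @return An object of class `contig_set`.
#' @export
contig_set <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("contig_id", "sequence") %in% names(records)))
    stop("`records` must have columns contig_id and sequence")
  if (anyDuplicated(records$contig_id)) stop("contig ids must be unique")
  if (any(grepl("[^ACGTN]", records$sequence)))
    stop("sequences must be over A/C/G/T/N (uppercase)")
  records$length <- nchar(records$sequence)
  if (is.null(records$gc))
    records$gc <- vapply(records$sequence, gc_content, numeric(1),
                         USE.NAMES = FALSE)
  rownames(records) <- NULL
  structure(records, class = c("contig_set", "data.frame"))
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs, %.1f kb total", nrow(x),
              sum(x$length) / 1000))
  if (!is.null(x$genome))
    cat(sprintf(", %d source genome(s)", length(unique(x$genome))))
  cat("\n")
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x)[, setdiff(names(x), "sequence")], 6)
    print.data.frame(show, digits = 4)
    if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more contigs\n")
  }
  invisible(x)
}
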