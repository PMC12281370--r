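#' Construct a TCR-beta repertoire
#'
#' A repertoire is a clonotype table keyed by (CDR3 amino-acid sequence,
#' V gene). Rows sharing a key are merged with counts summed; frequencies
#' are counts over the total read count and sum to 1.
#'
#' @param cdr3_aa character CDR3 amino-acid sequences (non-empty).
#' @param v_gene V-gene labels.
#' @param count positive integer clone counts.
#' @param sample_id optional label.
#' @return Object of class \code{"repertoire"}: a data.frame with columns
#'   \code{cdr3_aa}, \code{v_gene}, \code{count}, \code{frequency}
#'   (input order of first appearance preserved; ties are never reordered).
#' @export
repertoire <- function(cdr3_aa, v_gene, count, sample_id = NULL) {
  stopifnot(length(cdr3_aa) == length(v_gene),
            length(cdr3_aa) == length(count))
  if (length(cdr3_aa) == 0L) stop("empty repertoire")
  if (any(!nzchar(cdr3_aa)) || anyNA(cdr3_aa)) stop("empty CDR3 sequence")
  if (anyNA(count) || any(count < 1)) stop("counts must be >= 1")
  key <- paste(cdr3_aa, v_gene, sep = "\r")
  first <- !duplicated(key)
  tot <- tapply(as.numeric(count), factor(key, levels = key[first]), sum)
  d <- data.frame(cdr3_aa = cdr3_aa[first], v_gene = v_gene[first],
                  count = as.numeric(tot), stringsAsFactors = FALSE)
  d$frequency <- d$count / sum(d$count)
  structure(d, class = c("repertoire", "data.frame"),
            sample_id = sample_id)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("TCR-beta repertoire%s: %d clonotypes, %s reads\n",
              if (!is.null(attr(x, "sample_id")))
                paste0(" '", attr(x, "sample_id"), "'") else "",
              nrow(x), format(sum(x$count), big.mark = ",")))
  cat(sprintf("  Shannon entropy %.3f bits, clonality %.3f, D50 %d\n",
              shannon_entropy(x), clonality(x), d50(x)))
  invisible(x)
}

#' Read a clonotype table
#'
#' Accepts an AIRR-rearrangement-style TSV (columns \code{junction_aa},
#' \code{v_call}, \code{duplicate_count}) or a simple 3-column CSV
#' (\code{cdr3_aa}, \code{v_gene}, \code{count}); the dialect is detected
#' from the header.
#'
#' @param path file path.
#' @return A \code{\link{repertoire}}.
#' @export
read_repertoire <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[\t,]")[[1]]
  if ("junction_aa" %in% header) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    repertoire(d$junction_aa, d$v_call, d$duplicate_count,
               sample_id = basename(path))
  } else if ("cdr3_aa" %in% header) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    repertoire(d$cdr3_aa, d$v_gene, d$count, sample_id = basename(path))
  } else {
    stop("unrecognized clonotype table header: ",
         paste(header, collapse = ", "))
  }
}

#' Write a clonotype table
#'
#' @param rep a \code{\link{repertoire}}.
#' @param path output file.
#' @param format \code{"airr"} (TSV with junction_aa/v_call/duplicate_count)
#'   or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_repertoire <- function(rep, path, format = c("airr", "csv")) {
  format <- match.arg(format)
  if (format == "airr") {
    d <- data.frame(junction_aa = rep$cdr3_aa, v_call = rep$v_gene,
                    duplicate_count = rep$count)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    d <- data.frame(cdr3_aa = rep$cdr3_aa, v_gene = rep$v_gene,
                    count = rep$count)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Repertoire richness
#'
#' Number of unique clonotypes, a clonotype being a distinct
#' (CDR3 amino acid, V gene) pair.
#'
#' @param rep a \code{\link{repertoire}}.
#' @return Integer count.
#' @export
richness <- function(rep) {
  if (nrow(rep) == 0L) stop("empty repertoire")
  nrow(rep)
}

#' Shannon entropy (bits)
#'
#' \eqn{H = -\sum_i F_i \log_2 F_i} over clonotype frequencies, with
#' \eqn{0 \log 0 := 0}.
#'
#' @param rep a \code{\link{repertoire}} or a numeric frequency vector.
#' @return Entropy in bits; \code{log2(n)} for a uniform n-clone repertoire,
#'   0 for a monoclonal one.
#' @export
shannon_entropy <- function(rep) {
  f <- rep_freq(rep)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Clonality (1 - Pielou evenness)
#'
#' \eqn{1 - H/\log n} in a consistent logarithm base (base-invariant), in
#' [0, 1]: 0 for a perfectly even repertoire, 1 for a monoclonal one. A
#' single-clonotype repertoire returns 1 by convention (Pielou undefined at
#' n = 1).
#'
#' @inheritParams shannon_entropy
#' @return Clonality in [0, 1].
#' @export
clonality <- function(rep) {
  f <- rep_freq(rep)
  n <- length(f)
  if (n == 1L) return(1)
  1 - shannon_entropy(f) / log2(n)
}

#' D50 diversity
#'
#' Minimal number of top clonotypes whose cumulative frequency reaches 50%
#' of the repertoire. Frequency ties are broken by stable input order.
#'
#' @inheritParams shannon_entropy
#' @return Integer.
#' @export
d50 <- function(rep) {
  f <- rep_freq(rep)
  if (length(f) == 0L) stop("empty repertoire")
  cum <- cumsum(sort(f, decreasing = TRUE, method = "radix"))
  which(cum >= 0.5 - 1e-12)[1]
}

#' Clone-size homeostasis bins
#'
#' Assigns each clonotype by frequency to small (0, 1e-4], medium
#' (1e-4, 1e-3], large (1e-3, 1e-2] or hyperexpanded (1e-2, 1], and returns
#' the total frequency mass per bin (masses sum to 1).
#'
#' @inheritParams shannon_entropy
#' @param edges upper bin edges (right-closed), defaults
#'   \code{c(1e-4, 1e-3, 1e-2, 1)}.
#' @return Named numeric vector of per-bin masses.
#' @export
clone_size_bins <- function(rep, edges = c(small = 1e-4, medium = 1e-3,
                                           large = 1e-2,
                                           hyperexpanded = 1)) {
  f <- rep_freq(rep)
  if (length(f) == 0L) stop("empty repertoire")
  bin <- cut(f, breaks = c(0, unname(edges)), labels = names(edges),
             right = TRUE)
  mass <- tapply(f, bin, sum, default = 0)
  out <- stats::setNames(as.numeric(mass), names(edges))
  out[is.na(out)] <- 0
  out
}

#' Repertoire overlap
#'
#' Number of clonotype keys shared by two repertoires (symmetric), with the
#' Jaccard index as auxiliary statistic.
#'
#' @param rep_a,rep_b \code{\link{repertoire}} objects.
#' @return List: \code{shared}, \code{jaccard}.
#' @export
overlap <- function(rep_a, rep_b) {
  if (nrow(rep_a) == 0L || nrow(rep_b) == 0L) stop("empty repertoire")
  ka <- paste(rep_a$cdr3_aa, rep_a$v_gene, sep = "\r")
  kb <- paste(rep_b$cdr3_aa, rep_b$v_gene, sep = "\r")
  shared <- length(intersect(ka, kb))
  list(shared = shared,
       jaccard = shared / length(union(ka, kb)))
}

#' Track top clonotypes across samples
#'
#' Follows the reference repertoire's top-k clonotypes (by frequency, stable
#' ties) through an ordered series of samples, reporting each clonotype's
#' frequency in each sample (0 when absent).
#'
#' @param reference a \code{\link{repertoire}} whose top clones are tracked.
#' @param samples list of repertoires, in time order.
#' @param k number of top clonotypes (default 10); must not exceed the
#'   reference richness.
#' @return Numeric matrix, rows = top-k clonotype keys
#'   ("CDR3aa|Vgene"), columns = sample ids (or list names/indices).
#' @export
track_top <- function(reference, samples, k = 10) {
  if (k > richness(reference))
    stop("k exceeds the reference richness (", richness(reference), ")")
  ord <- order(-reference$frequency)  # stable: preserves input order on ties
  top <- reference[ord[seq_len(k)], , drop = FALSE]
  keys <- paste(top$cdr3_aa, top$v_gene, sep = "|")
  if (is.null(names(samples)))
    names(samples) <- vapply(seq_along(samples), function(i) {
      sid <- attr(samples[[i]], "sample_id")
      if (is.null(sid)) paste0("sample_", i) else sid
    }, character(1))
  m <- vapply(samples, function(s) {
    sk <- paste(s$cdr3_aa, s$v_gene, sep = "|")
    f <- s$frequency[match(keys, sk)]
    f[is.na(f)] <- 0
    f
  }, numeric(k))
  m <- matrix(m, nrow = k, dimnames = list(keys, names(samples)))
  m
}

#' Full metric set for one repertoire
#'
#' @inheritParams shannon_entropy
#' @return Named list: richness, shannon_entropy (bits), clonality, d50,
#'   clone_size_bins.
#' @export
repertoire_metrics <- function(rep) {
  list(richness = richness(rep),
       shannon_entropy = shannon_entropy(rep),
       clonality = clonality(rep),
       d50 = d50(rep),
       clone_size_bins = as.list(clone_size_bins(rep)))
}

rep_freq <- function(rep) {
  f <- if (inherits(rep, "repertoire")) rep$frequency else as.numeric(rep)
  if (any(f < 0)) stop("negative frequency")
  if (abs(sum(f) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(f)), ")")
  f
}
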