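## Gene-annotation simulator: non-overlapping gene models with HC/LC
## confidence classes inside given intervals.

#' Simulate a gene annotation with confidence classes
#'
#' Places exactly `n_genes` non-overlapping gene models inside each interval,
#' tagging `n_high` of them as high-confidence ("HC") and the rest as
#' low-confidence ("LC"). Gene lengths are gamma-distributed around
#' `mean_gene_len` and gaps between genes are drawn proportionally from the
#' remaining slack, so the layout fills the interval realistically.
#'
#' @param regions A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_genes`, `n_high`, `n_low`, and optionally `mean_gene_len`
#'   (default 3000 bp). Intervals must not overlap within a chromosome.
#' @param seed Integer seed; the layout is deterministic under it.
#' @return A `GRanges` of gene features with `ID`, `type = "gene"` and
#'   `confidence` ("HC"/"LC") metadata columns.
#' @examples
#' ann <- simulateAnnotation(data.frame(chrom = "2A", start = 0, end = 16.1e6,
#'                                      n_genes = 10, n_high = 4, n_low = 6))
#' table(ann$confidence)
#' @export
simulateAnnotation <- function(regions, seed = 1L) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "n_genes", "n_high", "n_low")
                %in% names(regions)))
  if (!("mean_gene_len" %in% names(regions)))
    regions$mean_gene_len <- 3000
  if (any(regions$n_high + regions$n_low != regions$n_genes))
    stop("confidence split must sum to n_genes in every interval")
  if (any(regions$n_genes < 0) || any(regions$end <= regions$start))
    stop("invalid interval or negative gene count")
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)]))
      stop(sprintf("overlapping intervals on %s", chr))
  }
  set.seed(as.integer(seed))
  pieces <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    row <- regions[k, ]
    n <- as.integer(row$n_genes)
    if (n == 0L) next
    widthBp <- row$end - row$start
    if (n * row$mean_gene_len > widthBp)
      stop(sprintf(
        "interval %s:%g-%g too small for %d genes of mean length %g",
        row$chrom, row$start, row$end, n, row$mean_gene_len))
    len <- pmax(150, round(rgamma(n, shape = 4, rate = 4 / row$mean_gene_len)))
    if (sum(len) > 0.95 * widthBp)
      len <- pmax(150, floor(len * 0.95 * widthBp / sum(len)))
    slack <- widthBp - sum(len)
    gapW <- rexp(n + 1L)
    gaps <- floor(slack * gapW / sum(gapW))
    starts <- row$start + cumsum(c(gaps[1L], len[-n] + gaps[-c(1L, n + 1L)]))
    conf <- rep("LC", n)
    conf[sample.int(n, as.integer(row$n_high))] <- "HC"
    pieces[[k]] <- data.frame(chrom = row$chrom, start = starts + 1,
                              width = len,
                              ID = sprintf("gene_%s_%05d", row$chrom,
                                           seq_len(n)),
                              type = "gene", confidence = conf)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    g <- GRanges()
    mcols(g) <- DataFrame(ID = character(0), type = character(0),
                          confidence = character(0))
    return(g)
  }
  df <- do.call(rbind, pieces)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  GRanges(df$chrom, IRanges(start = df$start, width = df$width),
          ID = df$ID, type = df$type, confidence = df$confidence)
}
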