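#' @rdname DepthProfile-class
#' @param x,object An object.
#' @export
setGeneric("profileWindows", function(x) standardGeneric("profileWindows"))

#' @rdname DepthProfile-class
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname DepthProfile-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname SnpTable-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname SnpTable-class
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname SnpTable-class
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname SnpTable-class
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname SnpTable-class
#' @param which `"ref"` or `"alt"`.
#' @export
setGeneric("alleleDepths", function(x, which = c("ref", "alt"))
  standardGeneric("alleleDepths"))

#' @rdname SnpTable-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SnpTable-class
#' @param side `"5"` or `"3"`.
#' @export
setGeneric("flankSeqs", function(x, side = c("5", "3"))
  standardGeneric("flankSeqs"))

#' @rdname TranslocationCall-class
#' @export
setGeneric("donorSegment", function(x) standardGeneric("donorSegment"))

#' @rdname TranslocationCall-class
#' @export
setGeneric("recipientSegment", function(x) standardGeneric("recipientSegment"))

#' @rdname TranslocationCall-class
#' @export
setGeneric("isNoCall", function(x) standardGeneric("isNoCall"))

## ---------------------------------------------------------------------------
## DepthProfile methods
## ---------------------------------------------------------------------------

#' @rdname DepthProfile-class
#' @export
setMethod("profileWindows", "DepthProfile", function(x) x@windows)

#' @rdname DepthProfile-class
#' @export
setMethod("windowSize", "DepthProfile", function(x) x@windowSize)

#' @rdname DepthProfile-class
#' @export
setMethod("isNormalized", "DepthProfile", function(x) x@normalized)

setMethod("show", "DepthProfile", function(object) {
  gr <- object@windows
  cat(sprintf("DepthProfile: %d windows (%g bp) on %d chromosome(s)%s\n",
              length(gr), object@windowSize,
              length(unique(as.character(seqnames(gr)))),
              if (object@normalized) ", normalized" else ""))
  cat(sprintf("  mean depth %.3g, range [%.3g, %.3g]\n",
              mean(gr$depth), min(gr$depth), max(gr$depth)))
})

## ---------------------------------------------------------------------------
## SnpTable methods
## ---------------------------------------------------------------------------

#' @rdname SnpTable-class
#' @export
setMethod("nSnps", "SnpTable", function(x) length(x@gr))

#' @rdname SnpTable-class
#' @export
setMethod("snpRanges", "SnpTable", function(x) x@gr)

#' @rdname SnpTable-class
#' @export
setMethod("refAllele", "SnpTable", function(x) x@ref)

#' @rdname SnpTable-class
#' @export
setMethod("altAllele", "SnpTable", function(x) x@alt)

#' @rdname SnpTable-class
#' @export
setMethod("alleleDepths", "SnpTable", function(x, which = c("ref", "alt")) {
  which <- match.arg(which)
  if (which == "ref") x@refDepth else x@altDepth
})

#' @rdname SnpTable-class
#' @export
setMethod("genotypes", "SnpTable", function(x) x@geno)

#' @rdname SnpTable-class
#' @export
setMethod("flankSeqs", "SnpTable", function(x, side = c("5", "3")) {
  side <- match.arg(side)
  if (side == "5") x@flank5 else x@flank3
})

#' @rdname SnpTable-class
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "SnpTable", function(x, i, j, ..., drop = FALSE) {
  new("SnpTable", gr = x@gr[i], ref = x@ref[i], alt = x@alt[i],
      refDepth = x@refDepth[i, , drop = FALSE],
      altDepth = x@altDepth[i, , drop = FALSE],
      geno = x@geno[i, , drop = FALSE],
      flank5 = x@flank5[i], flank3 = x@flank3[i])
})

setMethod("show", "SnpTable", function(object) {
  cat(sprintf("SnpTable: %d biallelic SNP(s), samples: %s\n",
              nSnps(object), paste(colnames(object@refDepth), collapse = ", ")))
  if (nSnps(object) > 0L) {
    chr <- unique(as.character(seqnames(object@gr)))
    cat(sprintf("  chromosome(s): %s; positions %d..%d\n",
                paste(chr, collapse = ", "),
                min(start(object@gr)), max(start(object@gr))))
  }
})

#' SNP identifiers of the form chrom_pos
#'
#' @param x A [SnpTable-class].
#' @return Character vector of `"<chrom>_<pos>"` identifiers.
#' @export
snpIds <- function(x) {
  stopifnot(is(x, "SnpTable"))
  paste(as.character(seqnames(x@gr)), start(x@gr), sep = "_")
}

## ---------------------------------------------------------------------------
## TranslocationCall methods
## ---------------------------------------------------------------------------

#' @rdname TranslocationCall-class
#' @export
setMethod("donorSegment", "TranslocationCall", function(x) x@donorSegment)

#' @rdname TranslocationCall-class
#' @export
setMethod("recipientSegment", "TranslocationCall",
          function(x) x@recipientSegment)

#' @rdname TranslocationCall-class
#' @export
setMethod("isNoCall", "TranslocationCall", function(x) x@noCall)

setMethod("show", "TranslocationCall", function(object) {
  if (object@noCall) {
    cat("TranslocationCall: no call (no qualifying distal segments)\n")
  } else {
    d <- object@donorSegment; r <- object@recipientSegment
    cat(sprintf("TranslocationCall: %s\n", object@name))
    cat(sprintf("  added  %s:%d-%d (%.1f Mb, %d windows)\n",
                as.character(seqnames(d)), start(d) - 1L, end(d),
                d$size_mb, d$n_windows))
    cat(sprintf("  deleted %s:%d-%d (%.1f Mb, %d windows)\n",
                as.character(seqnames(r)), start(r) - 1L, end(r),
                r$size_mb, r$n_windows))
  }
})
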