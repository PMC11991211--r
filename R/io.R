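## File-format boundary: depth TSV, VCF (vcfR), GFF3 (rtracklayer), flanks
## FASTA (Biostrings), segments BED, phenotype TSV. Coordinates are 0-based
## half-open in TSV/BED and 1-based in VCF/GFF3; conversion happens here.

#' @importFrom vcfR read.vcfR write.vcf extract.gt getFIX
#' @importClassesFrom vcfR vcfR
NULL

#' Write a depth profile as TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `depth`, tab
#' separated with a header line.
#'
#' @param profile A [DepthProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDepth <- function(profile, path) {
  stopifnot(is(profile, "DepthProfile"))
  gr <- profile@windows
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), depth = gr$depth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth profile from TSV
#'
#' Accepts either per-window records (`chrom`, `start`, `end`, `depth`;
#' 0-based half-open) or per-base triples (`chrom`, `pos`, `depth`; `pos`
#' 1-based) which are aggregated to window means over `windowSize` bp, with
#' uncovered positions counted as depth 0. Unsorted or overlapping windows
#' raise an error naming the offending line.
#'
#' @param path Input TSV (header optional).
#' @param windowSize Required for per-base input; optional otherwise.
#' @return A [DepthProfile-class].
#' @export
readDepth <- function(path, windowSize = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first[-1]))))
  df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  headerOffset <- as.integer(hasHeader)
  if (ncol(df) == 3L) {
    if (is.null(windowSize))
      stop("per-base depth input needs a windowSize to aggregate")
    names(df) <- c("chrom", "pos", "depth")
    pieces <- lapply(split(df, df$chrom), function(d) {
      win <- floor((d$pos - 1) / windowSize)
      agg <- tapply(d$depth, win, sum)
      w <- as.numeric(names(agg))
      data.frame(chrom = d$chrom[1], start = w * windowSize,
                 end = (w + 1) * windowSize,
                 depth = as.numeric(agg) / windowSize)
    })
    df <- do.call(rbind, pieces)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
  } else if (ncol(df) >= 4L) {
    names(df)[1:4] <- c("chrom", "start", "end", "depth")
    for (ch in unique(df$chrom)) {
      i <- which(df$chrom == ch)
      if (length(i) > 1L) {
        bad <- i[-1][diff(df$start[i]) <= 0]
        if (length(bad))
          stop(sprintf("unsorted windows at line %d", bad[1] + headerOffset))
        ov <- i[-1][df$start[i][-1] < df$end[i][-length(i)]]
        if (length(ov))
          stop(sprintf("overlapping windows at line %d", ov[1] + headerOffset))
      }
    }
  } else stop("depth TSV must have 3 (per-base) or 4 (per-window) columns")
  DepthProfile(df$chrom, df$start, df$end, df$depth, windowSize = windowSize)
}

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Write a SnpTable as VCF v4.2
#'
#' Emits one record per SNP with per-sample `GT:AD:DP` fields through
#' \pkg{vcfR} (output is bgzip-compressed when the path ends in `.gz`, plain
#' text otherwise).
#'
#' @param snps A [SnpTable-class].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(snps, path) {
  stopifnot(is(snps, "SnpTable"))
  n <- nSnps(snps)
  meta <- c("##fileformat=VCFv4.2",
            "##source=IntroKASP",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  fix <- cbind(CHROM = as.character(seqnames(snps@gr)),
               POS = as.character(start(snps@gr)),
               ID = snpIds(snps), REF = snps@ref, ALT = snps@alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  samples <- colnames(snps@refDepth)
  gtCols <- vapply(samples, function(s) {
    gt <- snps@geno[, s]
    gt[is.na(gt)] <- "./."
    sprintf("%s:%d,%d:%d", gt, snps@refDepth[, s], snps@altDepth[, s],
            snps@refDepth[, s] + snps@altDepth[, s])
  }, character(n))
  gt <- cbind(FORMAT = rep("GT:AD:DP", n),
              matrix(gtCols, nrow = n, dimnames = list(NULL, samples)))
  obj <- new("vcfR", meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(obj, file = path)
  } else {
    gz <- paste0(path, ".gz")
    vcfR::write.vcf(obj, file = gz)
    writeLines(readLines(gzfile(gz)), path)
    unlink(gz)
  }
  invisible(path)
}

#' Read a SnpTable from VCF
#'
#' Parses biallelic SNP records with per-sample `GT` and `AD` fields. A
#' sample-role map translates VCF sample names to the pipeline roles
#' (glaucous_bulk, nonglaucous_bulk, parent_donor, parent_recipient). A
#' record with a missing AD on some sample gets zero depths and a missing
#' call for that sample. Flanks are attached from `flanksFasta` when given.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param roleMap Named character vector `role = vcf_sample_name`; identity
#'   over the standard roles by default.
#' @param flanksFasta Optional path to the flanks FASTA written by
#'   [writeFlanksFasta()].
#' @return A [SnpTable-class].
#' @export
readSnpVcf <- function(path, roleMap = NULL, flanksFasta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  vcfSamples <- colnames(v@gt)[-1]
  if (is.null(roleMap))
    roleMap <- setNames(BULK_SAMPLES, BULK_SAMPLES)
  unknown <- setdiff(roleMap, vcfSamples)
  if (length(unknown))
    stop(sprintf("sample(s) not in VCF: %s", paste(unknown, collapse = ", ")))
  ad <- vcfR::extract.gt(v, "AD")
  gt <- vcfR::extract.gt(v, "GT")
  refD <- altD <- matrix(0L, n, length(roleMap),
                         dimnames = list(NULL, names(roleMap)))
  geno <- matrix(NA_character_, n, length(roleMap),
                 dimnames = list(NULL, names(roleMap)))
  for (role in names(roleMap)) {
    a <- ad[, roleMap[[role]]]
    parts <- strsplit(ifelse(is.na(a), "0,0", a), ",")
    refD[, role] <- as.integer(vapply(parts, `[`, character(1), 1L))
    altD[, role] <- as.integer(vapply(parts, `[`, character(1), 2L))
    g <- gt[, roleMap[[role]]]
    g[!is.na(g)] <- gsub("\\|", "/", g[!is.na(g)])
    g[g %in% c("./.", ".")] <- NA_character_
    geno[, role] <- g
  }
  if (!is.null(flanksFasta)) {
    fl <- readFlanksFasta(flanksFasta)
    idx <- match(paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fl$id)
    if (anyNA(idx)) stop("flanks FASTA does not cover every VCF record")
    flank5 <- fl$flank5[idx]
    flank3 <- fl$flank3[idx]
  } else {
    flank5 <- flank3 <- DNAStringSet(rep("", n))
  }
  new("SnpTable",
      gr = GRanges(fix[, "CHROM"],
                   IRanges(as.integer(fix[, "POS"]), width = 1L)),
      ref = fix[, "REF"], alt = fix[, "ALT"],
      refDepth = refD, altDepth = altD, geno = geno,
      flank5 = flank5, flank3 = flank3)
}

## ---------------------------------------------------------------------------
## FASTA flanks
## ---------------------------------------------------------------------------

#' Write per-SNP flanking sequences as FASTA
#'
#' One record per SNP named `<chrom>_<pos>`, holding 5' flank + ref base +
#' 3' flank; the record description carries `flank5=<len>` so the reader can
#' split the sequence back.
#'
#' @param snps A [SnpTable-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeFlanksFasta <- function(snps, path) {
  stopifnot(is(snps, "SnpTable"))
  seqs <- DNAStringSet(paste0(as.character(snps@flank5), snps@ref,
                              as.character(snps@flank3)))
  names(seqs) <- sprintf("%s flank5=%d", snpIds(snps),
                         Biostrings::width(snps@flank5))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read per-SNP flanks written by [writeFlanksFasta()]
#'
#' @param path FASTA path.
#' @return A list: `id`, `flank5`, `flank3` (`DNAStringSet`s), `snpBase`.
#' @export
readFlanksFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  f5len <- as.integer(sub("^.*flank5=(\\d+).*$", "\\1", hdr))
  if (anyNA(f5len)) stop("FASTA headers lack the flank5= length tag")
  flank5 <- Biostrings::subseq(seqs, 1L, f5len)
  snpBase <- as.character(Biostrings::subseq(seqs, f5len + 1L, f5len + 1L))
  flank3 <- Biostrings::subseq(seqs, f5len + 2L, Biostrings::width(seqs))
  names(flank5) <- names(flank3) <- id
  list(id = id, flank5 = flank5, flank3 = flank3, snpBase = snpBase)
}

## ---------------------------------------------------------------------------
## GFF3, BED, phenotype TSV
## ---------------------------------------------------------------------------

#' Write a gene annotation as GFF3
#'
#' @param annotation A `GRanges` with `ID`, `type` and `confidence` metadata
#'   (as produced by [simulateAnnotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Keeps `gene`-type features; genes without a `confidence` attribute are
#' kept (they still count toward totals) and reported through a warning.
#'
#' @param path GFF3 path.
#' @return A `GRanges` with a `confidence` metadata column (NA where absent).
#' @export
readGeneAnnotation <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  if (!is.null(g$type)) g <- g[as.character(g$type) == "gene"]
  if (is.null(g$confidence)) {
    warning("annotation has no confidence attribute on any gene")
    g$confidence <- NA_character_
  } else if (anyNA(g$confidence)) {
    warning(sprintf("%d gene(s) lack a confidence attribute",
                    sum(is.na(g$confidence))))
  }
  g
}

#' Write segments as BED
#'
#' BED-style 0-based half-open records with `state` as the name column and
#' `size_mb` as a fifth column.
#'
#' @param segments A `GRanges` from [segmentStates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSegmentsBed <- function(segments, path) {
  df <- data.frame(chrom = as.character(seqnames(segments)),
                   start = start(segments) - 1L, end = end(segments),
                   name = segments$state, size_mb = segments$size_mb)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED
#'
#' @param regions A `GRanges` from [callCandidateRegion()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = sprintf("peak_%g", regions$peak_pos),
                   score = round(1000 * pmin(1, pmax(0, regions$peak_delta))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the phenotype table as TSV
#'
#' @param phenotypes Data.frame from [simulateF2Bulks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
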