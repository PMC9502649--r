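# Readers and writers for the standard formats the pipeline touches:
# VCF 4.2 genotypes (via vcfR), TSV depth tables, BED6 region calls,
# FASTA via Biostrings, GFF3 gene models, and the Merqury-style QV
# conversion. BED and depth tables are 0-based half-open; VCF and GFF3
# stay 1-based per their standards.

#' Read a two-column sex map (individual id, M/F)
#'
#' @param path TSV with columns id and sex; no header required.
#' @return Named character vector id -> sex.
#' @export
read_sex_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) stop("sex map must have two columns: id, sex")
  sex <- toupper(trimws(df[[2]]))
  if (!all(sex %in% c("M", "F"))) stop("sex map values must be M or F")
  stats::setNames(sex, trimws(df[[1]]))
}

# map one diploid GT string to a genotype code
gt_to_code <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(-1L)
  parts <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || any(parts == ".")) return(-1L)  # half-calls
  a <- suppressWarnings(as.integer(parts))
  if (anyNA(a)) return(-1L)
  if (a[1] == 0 && a[2] == 0) 0L else if (a[1] != a[2]) 1L else 2L
}

#' Read a VCF into a genotype matrix
#'
#' Diploid GT fields are mapped to codes (0 hom-ref, 1 het, 2 hom-alt);
#' half-calls and `./.` become -1 (missing). Phased separators are
#' accepted and treated as unphased. Multi-allelic sites are preserved
#' with their full ALT string so downstream filtering can drop them.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @param sex_map named vector id -> "M"/"F" (see [read_sex_map()]);
#'   samples absent from the map are labelled `unknown`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sex_map = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  sex <- rep("unknown", length(samples))
  if (!is.null(sex_map)) {
    known <- samples %in% names(sex_map)
    sex[known] <- unname(sex_map[samples[known]])
  }
  codes <- matrix(vapply(as.vector(gt), gt_to_code, integer(1)),
                  nrow = nrow(gt))
  genotype_matrix(sites,
                  data.frame(id = samples, sex = sex,
                             stringsAsFactors = FALSE),
                  codes)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals$id), collapse = "\t")
  )
  gt_mat <- matrix(gt_str[as.character(gm$codes)], nrow = nrow(gm$codes))
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    format(gm$sites$qual, trim = TRUE), "PASS", ".", "GT",
    apply(gt_mat, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a depth table as TSV
#'
#' Long format: chrom, window_start, window_end, individual, mean_depth.
#' @param depth a [depth_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  stopifnot(inherits(depth, "depth_table"))
  long <- data.frame(
    chrom = rep(depth$windows$chrom, ncol(depth$values)),
    window_start = rep(depth$windows$start, ncol(depth$values)),
    window_end = rep(depth$windows$end, ncol(depth$values)),
    individual = rep(colnames(depth$values), each = nrow(depth$windows)),
    mean_depth = as.vector(depth$values),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV depth table
#'
#' @param path TSV with columns chrom, window_start, window_end,
#'   individual, mean_depth.
#' @return A [depth_table()].
#' @export
read_depth_table <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
  need <- c("chrom", "window_start", "window_end", "individual",
            "mean_depth")
  if (!all(need %in% names(long))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(long$chrom, long$window_start, long$window_end)
  wk <- !duplicated(key)
  windows <- data.frame(chrom = long$chrom[wk],
                        start = long$window_start[wk],
                        end = long$window_end[wk], stringsAsFactors = FALSE)
  inds <- unique(long$individual)
  vals <- matrix(NA_real_, nrow(windows), length(inds),
                 dimnames = list(NULL, inds))
  vals[cbind(match(key, key[wk]), match(long$individual, inds))] <-
    long$mean_depth
  if (anyNA(vals)) stop("depth table has missing window x individual cells")
  depth_table(windows, vals)
}

#' Write region calls as BED6
#'
#' The region class goes in the name column and the score is
#' `-log10(best site p-value)` capped at 1000. Calls must be sorted by
#' chromosome then start.
#'
#' @param calls a region-call data.frame from [delineate_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_calls <- function(calls, path) {
  header <- "# sdrscan region calls: chrom start end class score strand"
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(calls$chrom, calls$start)
  if (!identical(ord, seq_len(nrow(calls)))) {
    stop("region calls must be sorted by chrom, start")
  }
  score <- ifelse(is.na(calls$best_p) | calls$best_p <= 0, 1000,
                  pmin(1000, -log10(calls$best_p)))
  writeLines(c(header, paste(
    calls$chrom, format(calls$start, scientific = FALSE, trim = TRUE),
    format(calls$end, scientific = FALSE, trim = TRUE),
    calls$region_class, format(round(score, 4), trim = TRUE), ".",
    sep = "\t"
  )), path)
  invisible(path)
}

#' Read a BED6 region-call file written by [write_region_calls()]
#'
#' @param path BED path.
#' @return data.frame chrom, start, end, region_class, score.
#' @export
read_region_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_class = character(0),
                      score = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = parts[, 1], start = as.integer(parts[, 2]),
             end = as.integer(parts[, 3]), region_class = parts[, 4],
             score = as.numeric(parts[, 5]), stringsAsFactors = FALSE)
}

#' Convert a Phred-scaled consensus quality (QV) to percent accuracy
#'
#' `accuracy = 100 * (1 - 10^(-qv/10))`. Rounding is left to
#' presentation.
#'
#' @param qv Phred-scaled quality, >= 0.
#' @return Percent accuracy.
#' @examples
#' qv_to_accuracy(10)  # 90
#' round(qv_to_accuracy(25.96), 2)  # 99.75
#' @export
qv_to_accuracy <- function(qv) {
  if (any(qv < 0)) stop("qv must be non-negative")
  100 * (1 - 10^(-qv / 10))
}

#' Read protein-coding gene models from GFF3
#'
#' Collects CDS features per gene (via the `Parent`/`ID` attributes) into
#' [gene_model()] objects; segments are stored 0-based half-open in
#' transcription order.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gff <- ape::read.gff(path)
  cds <- gff[gff$type == "CDS", ]
  if (!nrow(cds)) return(list())
  parent <- sub(".*Parent=([^;]+).*", "\\1", cds$attributes)
  out <- lapply(split(cds, parent), function(g) {
    gene_model(
      gene_id = sub(".*Parent=([^;]+).*", "\\1", g$attributes[1]),
      chrom = as.character(g$seqid[1]),
      strand = as.character(g$strand[1]),
      segments = data.frame(start = g$start - 1L, end = g$end)
    )
  })
  out
}

#' Write gene models as GFF3
#'
#' @param models named list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    segs <- gm$segments
    lines <- c(lines, paste(
      gm$chrom, "sdrscan", "CDS", segs$start + 1L, segs$end, ".",
      gm$strand, gm$frame, paste0("Parent=", gm$gene_id), sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
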