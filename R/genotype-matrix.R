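#' Genotype matrix with site metadata and per-individual sex labels
#'
#' The substrate of the sex scan: a sites x individuals table of diploid
#' genotype codes (0 hom-ref, 1 het, 2 hom-alt, -1 missing) together with
#' site metadata (chromosome, 1-based position, alleles, quality) and a
#' declared sex (`M`, `F` or `unknown`) for every individual.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multi-allelic sites) and `qual`.
#' @param individuals data.frame with columns `id` and `sex`.
#' @param codes integer matrix, `nrow(sites)` x `nrow(individuals)`, entries
#'   in `{-1, 0, 1, 2}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, individuals, codes) {
  stopifnot(is.data.frame(sites), is.data.frame(individuals))
  needed <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(needed %in% names(sites))) {
    stop("sites must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(c("id", "sex") %in% names(individuals))) {
    stop("individuals must have columns id, sex")
  }
  if (!all(individuals$sex %in% c("M", "F", "unknown"))) {
    stop("individual sex must be one of M, F, unknown")
  }
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(sites) || ncol(codes) != nrow(individuals)) {
    stop("codes dimensions must be sites x individuals")
  }
  if (!all(codes %in% c(-1L, 0L, 1L, 2L))) {
    stop("genotype codes must be in {-1, 0, 1, 2}")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("site positions must be strictly increasing within chromosome ", ch)
    }
  }
  colnames(codes) <- individuals$id
  structure(
    list(sites = sites, individuals = individuals, codes = codes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x",
      nrow(x$individuals), "individuals (",
      sum(x$individuals$sex == "M"), "M /",
      sum(x$individuals$sex == "F"), "F )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), nrow(x$individuals))

#' Subset a genotype matrix by sites and/or individuals
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer or logical index into the site rows (default all).
#' @param individuals character ids, or integer/logical index (default all).
#' @return A new `genotype_matrix`; the input is not modified.
#' @export
subset_genotypes <- function(gm, sites = NULL, individuals = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- sites %||% seq_len(nrow(gm$sites))
  if (is.character(individuals)) {
    ii <- match(individuals, gm$individuals$id)
    if (anyNA(ii)) stop("unknown individual id(s): ",
                        paste(individuals[is.na(ii)], collapse = ", "))
  } else {
    ii <- individuals %||% seq_len(nrow(gm$individuals))
  }
  genotype_matrix(
    gm$sites[si, , drop = FALSE],
    gm$individuals[ii, , drop = FALSE],
    gm$codes[si, ii, drop = FALSE]
  )
}

#' Per-window sequencing depth table
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open, non-overlapping within chromosome).
#' @param values numeric matrix of mean depth, windows x individuals; column
#'   names are individual ids.
#' @return An object of class `depth_table`.
#' @export
depth_table <- function(windows, values) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end") %in% names(windows)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(windows)) stop("values rows must match windows")
  if (any(values < 0)) stop("depth values must be non-negative")
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    w <- w[order(w$start), ]
    if (any(w$end <= w$start)) stop("empty window on ", ch)
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
      stop("overlapping windows on ", ch)
    }
  }
  structure(list(windows = windows, values = values), class = "depth_table")
}

#' @export
print.depth_table <- function(x, ...) {
  cat("depth_table:", nrow(x$windows), "windows x",
      ncol(x$values), "individuals\n")
  invisible(x)
}
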