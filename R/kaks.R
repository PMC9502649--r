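# Nei-Gojobori (1986) synonymous/nonsynonymous divergence with
# Jukes-Cantor correction. Site fractions and mutational pathways both
# exclude changes through stop codons; multi-difference codons are
# averaged over all orderings of single steps.

.gencode_cache <- new.env(parent = emptyenv())

get_gencode <- function() {
  if (is.null(.gencode_cache$code)) {
    .gencode_cache$code <- as.list(Biostrings::GENETIC_CODE)
  }
  .gencode_cache$code
}

codon_aa <- function(codon) {
  aa <- get_gencode()[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# per-codon synonymous/nonsynonymous site counts, stop-excluded convention
codon_sites <- function(codon) {
  code <- get_gencode()
  aa <- code[[codon]]
  if (is.null(aa) || aa == "*") return(c(S = NA_real_, N = NA_real_))
  s <- n <- 0
  for (p in 1:3) {
    base <- substring(codon, p, p)
    alts <- setdiff(DNA_BASES, base)
    syn <- nonstop <- 0L
    for (b in alts) {
      mut <- codon
      substring(mut, p, p) <- b
      aam <- code[[mut]]
      if (aam == "*") next
      nonstop <- nonstop + 1L
      if (aam == aa) syn <- syn + 1L
    }
    if (nonstop > 0) {
      s <- s + syn / nonstop
      n <- n + (nonstop - syn) / nonstop
    }
  }
  c(S = s, N = n)
}

# pathway-averaged synonymous/nonsynonymous differences between two sense
# codons; paths through stop codons are excluded. Returns c(sd, nd) or NA
# if every path is blocked.
codon_differences <- function(c1, c2) {
  code <- get_gencode()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(diff_pos) else {
    if (d == 2) list(diff_pos, rev(diff_pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) diff_pos[o])
    }
  }
  sd_tot <- nd_tot <- 0
  n_valid <- 0L
  for (path in perms) {
    cur <- c1
    sd <- nd <- 0
    ok <- TRUE
    for (p in path) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p <= 0) return(0)
  if (p >= 0.75) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks between a codon-aligned CDS pair
#'
#' Synonymous site fractions are computed per codon under the standard
#' genetic code with stop-codon mutations excluded from both pathways and
#' site denominators; codons differing at several positions are averaged
#' over all orderings of single steps; `pS = Sd/S`, `pN = Nd/N` are
#' corrected with Jukes-Cantor, `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param x,y codon-aligned CDS strings of equal length divisible by 3
#'   (gapped codons `---` are excluded; see [align_codons()]).
#' @return An object of class `gametolog_pair`: list with `Sd`, `Nd`,
#'   `S`, `N`, `ps`, `pn`, `Ks`, `Ka`, `ka_ks` (NA when Ks is 0 or
#'   saturated), `n_codons` used, and `saturated` flag.
#' @export
ng86_ka_ks <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("sequences must be aligned (equal length)")
  if (nchar(x) %% 3 != 0) stop("aligned length must be divisible by 3")
  n_cod <- nchar(x) / 3
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cx <- substring(x, starts, starts + 2L)
  cy <- substring(y, starts, starts + 2L)
  code <- get_gencode()
  usable <- !grepl("[^ACGT]", cx) & !grepl("[^ACGT]", cy)
  cx <- cx[usable]
  cy <- cy[usable]
  sense <- vapply(cx, function(cc) code[[cc]] != "*", logical(1),
                  USE.NAMES = FALSE) &
    vapply(cy, function(cc) code[[cc]] != "*", logical(1),
           USE.NAMES = FALSE)
  cx <- cx[sense]
  cy <- cy[sense]
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (i in seq_along(cx)) {
    dd <- codon_differences(cx[i], cy[i])
    if (anyNA(dd)) next  # every pathway runs through a stop
    s1 <- codon_sites(cx[i])
    s2 <- codon_sites(cy[i])
    S <- S + (s1[["S"]] + s2[["S"]]) / 2
    N <- N + (s1[["N"]] + s2[["N"]]) / 2
    Sd <- Sd + dd[["sd"]]
    Nd <- Nd + dd[["nd"]]
    used <- used + 1L
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  structure(
    list(Sd = Sd, Nd = Nd, S = S, N = N, ps = ps, pn = pn,
         Ks = Ks, Ka = Ka,
         ka_ks = if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks
                 else NA_real_,
         n_codons = used,
         saturated = is.na(Ks) || is.na(Ka)),
    class = "gametolog_pair"
  )
}

#' @export
print.gametolog_pair <- function(x, ...) {
  cat(sprintf(
    "NG86: Sd=%.3f Nd=%.3f S=%.2f N=%.2f Ks=%s Ka=%s\n",
    x$Sd, x$Nd, x$S, x$N,
    ifelse(is.na(x$Ks), "saturated", sprintf("%.4f", x$Ks)),
    ifelse(is.na(x$Ka), "saturated", sprintf("%.4f", x$Ka))
  ))
  invisible(x)
}
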