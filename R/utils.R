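#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n n_distinct across all_of
#'   distinct rename row_number slice pull if_else count first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median qnbinom qpois pnorm rnbinom rpois rbinom runif
#'   quantile complete.cases lm coef cor setNames
#' @importFrom utils head data
NULL

#' Canonicalize an HLA allele string
#'
#' Maps the notations commonly mixed in panel sheets and haplotype tables --
#' compact (`"A0301"`), prefixed (`"HLA-A*03:01"`), or formal (`"A*03:01"`) --
#' onto the canonical two-field form `"A*03:01"` (locus, `*`, zero-padded
#' two-digit fields separated by `:`). Matching of a pMHC's restricting allele
#' against donor haplotypes is done on this canonical form, so it is
#' representation-independent.
#'
#' @param x Character vector of allele strings.
#' @return Character vector of canonical alleles, same length as `x`.
#' @examples
#' canonicalize_hla(c("A0301", "HLA-A*03:01", "B0702"))
#' @export
canonicalize_hla <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    orig <- s
    s <- trimws(s)
    s <- sub("^HLA-", "", s, ignore.case = TRUE)
    if (grepl("*", s, fixed = TRUE)) {
      parts <- strsplit(s, "*", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(parts[1])) {
        stop("unparseable HLA allele: '", orig, "'", call. = FALSE)
      }
      locus <- parts[1]
      fields <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
      if (length(fields) == 1L) {
        fields <- .split_compact_fields(fields, orig)
      }
    } else {
      m <- regmatches(s, regexec("^([A-Za-z]+)([0-9]{4})$", s))[[1]]
      if (length(m) != 3L) {
        stop("unparseable HLA allele: '", orig, "'", call. = FALSE)
      }
      locus <- m[2]
      fields <- c(substr(m[3], 1, 2), substr(m[3], 3, 4))
    }
    if (length(fields) < 2L || !all(grepl("^[0-9]+$", fields))) {
      stop("unparseable HLA allele: '", orig, "'", call. = FALSE)
    }
    fields <- formatC(as.integer(fields[1:2]), width = 2, flag = "0")
    paste0(toupper(locus), "*", fields[1], ":", fields[2])
  }, character(1), USE.NAMES = FALSE)
}

.split_compact_fields <- function(f, orig) {
  if (!grepl("^[0-9]{4}$", f)) {
    stop("unparseable HLA allele: '", orig, "'", call. = FALSE)
  }
  c(substr(f, 1, 2), substr(f, 3, 4))
}

# Parse a haplotype cell like "A0201;A0301;B0702" into canonical alleles.
parse_haplotype <- function(x, sep = "[;,/ ]+") {
  lapply(strsplit(trimws(x), sep), function(a) {
    a <- a[nzchar(a)]
    unique(canonicalize_hla(a))
  })
}

# Lenient logical parser for "True"/"true"/"TRUE"/"False" spellings.
parse_flexible_logical <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  out
}

tp_message <- function(...) {
  message("[tcrpair] ", ...)
}
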