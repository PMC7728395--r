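# Readers and writers for the standard formats the pipeline touches.
# Internal convention everywhere downstream: 0-based half-open intervals on
# the plus strand; BLAST tabular input is 1-based inclusive and may have
# descending subject coordinates on minus-strand hits.

#' Read a 12-column tabular homology hit file
#'
#' Parses the standard 12-column tabular output of a nucleotide or
#' translated homology search (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score).  Extra columns are ignored.
#'
#' Coordinates are converted from 1-based inclusive to 0-based half-open.
#' Descending subject coordinates are flipped and the hit flagged as minus
#' strand; the identity column is rescaled from percent to a fraction.
#'
#' @param path path to a tab-separated hit table without header.
#' @param search_kind `"nucleotide"` or `"translated"`; recorded per hit.
#' @return a `data.frame` of normalized HSPs with columns `query_id`,
#'   `subject_id`, `percent_identity` (fraction in \[0,1\]), `aln_length`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open,
#'   plus-strand ordered), `strand`, `evalue`, `bit_score`, `search_kind`.
#' @export
read_blast_tab <- function(path, search_kind = c("nucleotide", "translated")) {
  search_kind <- match.arg(search_kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hsp_table(search_kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 12)) {
    bad <- which(n_col < 12)[1]
    stop("malformed hit row at line ", bad, ": expected 12 tab-separated ",
         "columns, found ", n_col[bad])
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line ", which(is.na(v))[1])
    }
    v
  }
  q1 <- num(7, "query start"); q2 <- num(8, "query end")
  s1 <- num(9, "subject start"); s2 <- num(10, "subject end")
  strand <- rep("+", length(lines))
  flip_q <- q1 > q2
  if (any(flip_q)) {
    tmp <- q1[flip_q]; q1[flip_q] <- q2[flip_q]; q2[flip_q] <- tmp
    strand[flip_q] <- "-"
  }
  flip_s <- s1 > s2
  if (any(flip_s)) {
    tmp <- s1[flip_s]; s1[flip_s] <- s2[flip_s]; s2[flip_s] <- tmp
    strand[flip_s] <- ifelse(strand[flip_s] == "+", "-", "+")
  }
  pid <- num(3, "identity") / 100
  bit <- num(12, "bit score")
  if (any(bit < 0)) stop("negative bit score at line ", which(bit < 0)[1])
  if (any(pid < 0 | pid > 1)) {
    stop("identity outside [0,100] at line ", which(pid < 0 | pid > 1)[1])
  }
  data.frame(
    query_id = vapply(fields, `[[`, "", 1),
    subject_id = vapply(fields, `[[`, "", 2),
    percent_identity = pid,
    aln_length = num(4, "alignment length"),
    q_start = q1 - 1, q_end = q2,
    s_start = s1 - 1, s_end = s2,
    strand = strand,
    evalue = num(11, "e-value"),
    bit_score = bit,
    search_kind = search_kind,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
empty_hsp_table <- function(search_kind = "nucleotide") {
  data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), aln_length = numeric(0),
    q_start = numeric(0), q_end = numeric(0),
    s_start = numeric(0), s_end = numeric(0),
    strand = character(0), evalue = numeric(0), bit_score = numeric(0),
    search_kind = character(0), stringsAsFactors = FALSE
  )
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are returned verbatim (case preserved); comparison operations
#' elsewhere in the package case-fold.  Duplicate record ids are an error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence wrapping (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (length(records) && is.null(names(records))) {
    stop("records must be named")
  }
  con <- file(path, open = "wb")   # byte output => deterministic files
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq.int(1, n, by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, n)), con)
  }
  invisible(path)
}

#' Normalize a sequence alphabet to A/C/G/T/N uppercase
#'
#' Other IUPAC codes are mapped to `N` with a warning; used before
#' divergence statistics, which ignore N-containing columns.
#'
#' @param x character vector of sequences.
#' @return uppercase sequences over the A,C,G,T,N alphabet.
#' @export
normalize_alphabet <- function(x) {
  up <- toupper(x)
  cleaned <- gsub("[^ACGTN-]", "N", up)
  if (any(cleaned != up)) {
    warning("ambiguous IUPAC codes mapped to N")
  }
  cleaned
}

#' Read a taxon-pair synonymous rate table
#'
#' Tab-separated with header; columns `taxon_pair_class` and `r`
#' (substitutions per synonymous site per million years).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `taxon_pair_class`, `r`.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_pair_class", "r") %in% names(tab))) {
    stop("rate table needs columns 'taxon_pair_class' and 'r'")
  }
  if (any(!is.finite(tab$r)) || any(tab$r <= 0)) {
    stop("rates must be finite and > 0")
  }
  tab[, c("taxon_pair_class", "r")]
}

#' Read a species-pair divergence time table
#'
#' Tab-separated with header; columns `species_a`, `species_b`,
#' `divergence_my` (million years).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with the three columns above.
#' @export
read_divergence_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_a", "species_b", "divergence_my")
  if (!all(need %in% names(tab))) {
    stop("divergence table needs columns ", paste(need, collapse = ", "))
  }
  if (any(tab$divergence_my <= 0)) stop("divergence times must be > 0")
  tab[, need]
}

#' Look up the divergence time of a species pair
#'
#' @param tab table from [read_divergence_table()].
#' @param a,b species labels (order-free).
#' @return divergence time in million years.
#' @export
get_divergence <- function(tab, a, b) {
  hit <- (tab$species_a == a & tab$species_b == b) |
    (tab$species_a == b & tab$species_b == a)
  if (!any(hit)) stop("no divergence time for pair ", a, " / ", b)
  tab$divergence_my[which(hit)[1]]
}

#' Read a binary species range-overlap matrix
#'
#' Tab-separated with header row and row names.  The matrix must be
#' symmetric, binary, with a unit diagonal (a species overlaps itself).
#'
#' @param path path to the TSV file.
#' @return symmetric binary integer matrix.
#' @export
read_overlap_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("overlap matrix must be square with matching row/column names")
  }
  if (!all(m %in% c(0, 1))) stop("overlap matrix must be binary (0/1)")
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    stop("overlap matrix asymmetric at ", rownames(m)[asym[1, 1]], " / ",
         colnames(m)[asym[1, 2]])
  }
  if (any(diag(m) != 1)) stop("overlap matrix diagonal must be 1")
  storage.mode(m) <- "integer"
  m
}

#' Write genomic intervals as BED
#'
#' Intervals are already 0-based half-open internally, which is the native
#' BED convention, so no coordinate shift is applied.
#'
#' @param intervals `data.frame` with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy start < end")
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$contig, as.integer(intervals$start),
                   as.integer(intervals$end), name, as.character(score),
                   strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Minimal TOML-style dialect: one `key = value` per line, `#` comments,
#' optional `[section]` headers which prefix keys as `section.key`.
#' Values are parsed as numbers, `true`/`false`, or (optionally quoted)
#' strings.
#'
#' @param path path to the configuration file.
#' @return named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("cannot parse config line: ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2, nchar(val) - 1)
    } else if (tolower(val) %in% c("true", "false")) {
      val <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- val
  }
  out
}
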