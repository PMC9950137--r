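#' Gapped amino-acid alignment container
#'
#' A light container for a protein multiple sequence alignment: a character
#' matrix over the 20 amino acids plus the gap character \code{"-"} (and
#' \code{"X"} for unknown residues, which is permitted but flagged), with
#' unique sequence identifiers as row names.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param matrix Character matrix (sequences x columns) of single residues.
#' @return An object of class \code{aa_alignment} with elements \code{ids},
#'   \code{matrix} (rownames set to \code{ids}) and \code{n_sites}.
#' @export
aa_alignment <- function(ids, matrix) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.matrix(matrix) || nrow(matrix) != length(ids)) {
    stop("matrix must have one row per id")
  }
  matrix[] <- toupper(matrix)
  bad <- array(!(matrix %in% c(AA20, GAP_CHAR, UNKNOWN_CHAR)), dim(matrix))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal character '%s' in sequence '%s' at column %d",
                 matrix[w[1], w[2]], ids[w[1]], w[2]))
  }
  rownames(matrix) <- ids
  structure(list(ids = ids, matrix = matrix, n_sites = ncol(matrix)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d sites\n",
              length(x$ids), x$n_sites))
  invisible(x)
}

#' Read a gapped protein FASTA alignment
#'
#' Wraps \code{Biostrings::readBStringSet} and validates the result as an
#' alignment: equal row lengths, unique ids, alphabet restricted to the 20
#' amino acids plus gap (\code{X} allowed, flagged downstream as missing).
#' Lowercase is normalized to uppercase. The id is the first whitespace
#' token of the FASTA header.
#'
#' @param path Path to a FASTA file.
#' @return An \code{\link{aa_alignment}}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    ref <- lens[1]
    off <- ids[lens != ref][1]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 off, lens[ids == off][1], ref))
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  aa_alignment(ids, mat)
}

#' Write an alignment as FASTA
#'
#' @param alignment An \code{\link{aa_alignment}}.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(alignment, path, width = 60) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' Sequential relaxed PHYLIP (id, whitespace, full sequence per line), for
#' interoperability with phylogenetics tools.
#'
#' @inheritParams write_fasta
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(alignment, path) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(alignment$ids), alignment$n_sites), con)
  writeLines(paste(format(alignment$ids, width = max(nchar(alignment$ids)) + 2),
                   seqs, sep = ""), con)
  invisible(path)
}

#' Map between alignment columns and ungapped residue positions
#'
#' Builds the bidirectional, strictly monotone mapping between 1-based
#' alignment columns and 1-based ungapped residue numbering of one named
#' sequence. Gap columns of that sequence map to no residue (\code{NA}).
#'
#' @param alignment An \code{\link{aa_alignment}}.
#' @param id Sequence identifier whose residue numbering defines the map.
#' @return A \code{coordinate_map}: list with \code{id},
#'   \code{col_to_res} (length \code{n_sites}, \code{NA} at gap columns) and
#'   \code{res_to_col} (length = number of residues).
#' @export
build_coordinate_map <- function(alignment, id) {
  if (!id %in% alignment$ids) stop("unknown id: ", id)
  row <- alignment$matrix[id, ]
  present <- row != GAP_CHAR
  col_to_res <- rep(NA_integer_, length(row))
  col_to_res[present] <- seq_len(sum(present))
  structure(list(id = id,
                 col_to_res = col_to_res,
                 res_to_col = which(present)),
            class = "coordinate_map")
}

#' Column for a residue position
#' @param map A \code{coordinate_map}.
#' @param res 1-based residue position(s).
#' @return 1-based alignment column(s).
#' @export
residue_to_column <- function(map, res) {
  if (any(res < 1 | res > length(map$res_to_col))) {
    stop("residue position out of range")
  }
  map$res_to_col[res]
}

#' Residue position for a column
#' @param map A \code{coordinate_map}.
#' @param col 1-based alignment column(s).
#' @return 1-based residue position(s); \code{NA} for gap columns.
#' @export
column_to_residue <- function(map, col) {
  if (any(col < 1 | col > length(map$col_to_res))) {
    stop("alignment column out of range")
  }
  map$col_to_res[col]
}

# closed vocabularies for the structural annotation table
STRUCT_CATEGORIES <- c("active_site", "tunnel", "FAD_proximal",
                       "NADPH_shell1", "NADPH_shell2", "other")
STRUCT_LOCATIONS <- c("surface", "core")
STRUCT_DOMAINS <- c("FAD_binding", "NADPH_binding", "insertion_80res")

#' Read a per-residue structural annotation table
#'
#' Tab-delimited table with header
#' \code{position<TAB>category<TAB>location<TAB>domain}; positions are
#' 1-based ungapped residue numbers of the reference (ancestor) sequence.
#' Categories come from closed vocabularies: category in
#' \code{active_site, tunnel, FAD_proximal, NADPH_shell1, NADPH_shell2,
#' other}; location in \code{surface, core}; domain in
#' \code{FAD_binding, NADPH_binding, insertion_80res}.
#'
#' @param path Path to the TSV file.
#' @param max_position Optional sequence length; positions beyond it error.
#' @return A data.frame with validated columns.
#' @export
read_annotations <- function(path, max_position = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "category", "location", "domain")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  ann$position <- as.integer(ann$position)
  if (any(is.na(ann$position)) || any(ann$position < 1)) {
    stop("positions must be positive integers")
  }
  if (!is.null(max_position) && any(ann$position > max_position)) {
    stop("annotated position beyond sequence length ", max_position)
  }
  chk <- function(col, vocab) {
    bad <- setdiff(unique(ann[[col]]), vocab)
    if (length(bad)) stop("invalid ", col, ": ", paste(bad, collapse = ", "))
  }
  chk("category", STRUCT_CATEGORIES)
  chk("location", STRUCT_LOCATIONS)
  chk("domain", STRUCT_DOMAINS)
  ann
}
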