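#' @keywords internal
"_PACKAGE"

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
AA_VALID <- c(AA20, "X")

#' Construct a protein record
#'
#' A protein record holds a unique identifier, a free-text species tag and an
#' upper-case amino-acid sequence over the 20 standard residues plus `X`
#' (unknown residue, as found in translated-genome predictions). `X` never
#' matches a consensus position and never counts as identical or similar in
#' motif scoring.
#'
#' @param id Record identifier (non-empty string).
#' @param sequence Amino-acid sequence; coerced to upper case. `*` stop
#'   characters are stripped with a warning.
#' @param species Optional species tag (may be empty).
#' @return An object of class `protein_record` with elements `id`, `species`
#'   and `sequence`.
#' @export
protein_record <- function(id, sequence, species = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (grepl("*", sequence, fixed = TRUE)) {
    warning(sprintf("record '%s': stripping '*' stop character(s)", id))
    sequence <- gsub("*", "", sequence, fixed = TRUE)
  }
  if (!nzchar(sequence))
    stop(sprintf("record '%s': empty sequence", id))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_VALID)
  if (length(bad))
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, chars[bad[1]], bad[1]))
  structure(list(id = id, species = species, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s (%d aa)\n", x$id,
              if (nzchar(x$species)) paste0(" [", x$species, "]") else "",
              nchar(x$sequence)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a list of [protein_record()] objects.
#' The portion of the description line after the first whitespace is stored
#' as the species tag. Record order is preserved. Residues outside the 20
#' amino acids plus `X` raise an error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of `protein_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ",
         ids[duplicated(ids)][1])
  recs <- vector("list", length(aas))
  for (i in seq_along(aas)) {
    recs[[i]] <- protein_record(ids[i], as.character(aas[[i]]), species[i])
  }
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records A list of `protein_record` objects.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(length(records) >= 1L)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$species)) paste(r$id, r$species) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a rooted species tree in newick format
#'
#' Wraps [ape::read.tree()] and enforces the requirements of the parsimony
#' module: leaf labels must be unique and the tree must be rooted (the root
#' may carry any number of children >= 2; a basal polytomy of 3+ children is
#' still treated as the root of a rooted tree for scenario evaluation).
#' Internal node labels are retained as candidate origin points.
#'
#' @param path Path to a newick file (or a newick string containing ";").
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("newick parse error (unbalanced parentheses?)")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a gene-family presence/absence table
#'
#' Two-column whitespace- or tab-delimited text: taxon name and 0/1.
#' Returns a named logical vector (`TRUE` = present). Values outside
#' \{0, 1\} and duplicated taxa are errors.
#'
#' @param path Path to the table.
#' @return Named logical vector, one element per taxon.
#' @export
read_presence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("taxon", "present"),
                           colClasses = c("character", "character"))
  if (nrow(tab) == 0L) stop("empty presence table: ", path)
  if (anyDuplicated(tab$taxon))
    stop("duplicate taxon in presence table: ",
         tab$taxon[duplicated(tab$taxon)][1])
  bad <- which(!tab$present %in% c("0", "1"))
  if (length(bad))
    stop(sprintf("presence value for taxon '%s' must be 0 or 1, got '%s'",
                 tab$taxon[bad[1]], tab$present[bad[1]]))
  stats::setNames(tab$present == "1", tab$taxon)
}

#' Check a presence map against its companion tree
#'
#' Every taxon named in the presence map must exist as a leaf label of the
#' tree, and every leaf must have a presence state.
#'
#' @param presence Named logical vector from [read_presence_table()].
#' @param tree An [ape::phylo] tree.
#' @return `presence`, invisibly, reordered to the tree's tip order.
#' @export
validate_presence <- function(presence, tree) {
  missing_in_tree <- setdiff(names(presence), tree$tip.label)
  if (length(missing_in_tree))
    stop("taxa in presence map absent from tree: ",
         paste(missing_in_tree, collapse = ", "))
  missing_state <- setdiff(tree$tip.label, names(presence))
  if (length(missing_state))
    stop("leaves without a presence state: ",
         paste(missing_state, collapse = ", "))
  invisible(presence[tree$tip.label])
}
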