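#' NCBI translation tables and derived structures
#'
#' Accessors for the genetic code tables shipped with the package (via
#' Biostrings' copy of the NCBI translation tables) plus derived structures
#' used throughout: the stop-codon set and the partition of the 64 codons
#' into synonymous families.
#'
#' @name genetic_codes
NULL

# Shipped NCBI translation-table ids (as integers). Tables differ in their
# stop sets, which is what the hidden-stop scanner cares about.
.SHIPPED_TABLE_IDS <- c(1:6, 9:16, 21:25)

.BASES <- c("A", "C", "G", "T")

#' All 64 DNA codons in fixed lexicographic (A,C,G,T) order
#'
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  g <- expand.grid(n3 = .BASES, n2 = .BASES, n1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$n1, g$n2, g$n3)
}

#' List the shipped NCBI translation tables
#'
#' @return A data.frame with columns `table_id`, `name`, `stop_codons`
#'   (comma-separated).
#' @export
list_genetic_codes <- function() {
  rows <- lapply(.SHIPPED_TABLE_IDS, function(id) {
    code <- get_genetic_code(id)
    data.frame(table_id = id, name = code$name,
               stop_codons = paste(sort(code$stop_set), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Retrieve a genetic code table by NCBI translation-table id
#'
#' The returned object maps every one of the 64 DNA codons (uppercase, T not
#' U) to a single-letter amino acid, with `*` for stop. The stop set drives
#' the hidden-stop scanner; the start set is informational only.
#'
#' @param table_id Integer NCBI translation-table number (one of 1-6, 9-16,
#'   21-25).
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `name`, `codon_map` (named character of length 64), `stop_set`,
#'   `start_set`.
#' @examples
#' get_genetic_code(1)$stop_set   # TAA TAG TGA
#' get_genetic_code(2)$stop_set   # TAA TAG AGA AGG
#' @export
get_genetic_code <- function(table_id) {
  if (length(table_id) != 1L || is.na(suppressWarnings(as.integer(table_id))))
    stop("table_id must be a single integer")
  table_id <- as.integer(table_id)
  if (!table_id %in% .SHIPPED_TABLE_IDS)
    stop("unknown translation table ", table_id, "; available ids: ",
         paste(.SHIPPED_TABLE_IDS, collapse = ", "))
  id_chr <- as.character(table_id)
  map <- Biostrings::getGeneticCode(id_chr)
  alt <- attr(map, "alt_init_codons")
  map <- map[all_codons()]            # fixed order, drop attributes
  attributes(map) <- list(names = all_codons())
  tbl <- Biostrings::GENETIC_CODE_TABLE
  name <- tbl$name[match(id_chr, tbl$id)]
  structure(list(
    table_id  = table_id,
    name      = name,
    codon_map = map,
    stop_set  = unname(names(map)[map == "*"]),
    start_set = unique(c("ATG", alt))
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, "-", x$name, "\n")
  cat("  stop codons:", paste(x$stop_set, collapse = " "), "\n")
  cat("  start codons:", paste(x$start_set, collapse = " "), "\n")
  invisible(x)
}

#' Synonymous codon families of a genetic code
#'
#' Partitions the 64 codons by encoded amino acid; the stop codons form
#' their own family keyed `*`.
#'
#' @param code A `genetic_code` object.
#' @return Named list of character vectors; names are single-letter amino
#'   acids (plus `*`), values the codons of that family.
#' @export
synonymous_families <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  split(names(code$codon_map), unname(code$codon_map))
}
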