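# Protein-level variant notation: parsing, amino-acid substitution matrices,
# and collagen Gly-X-Y periodicity.

#' Amino-acid code table
#'
#' The 20 standard residues plus `X`/`Xaa` (unknown) and `*`/`Ter` (stop),
#' as a bijection between one-letter and three-letter codes.
#'
#' @return A tibble with columns `code1` and `code3`.
#' @export
amino_acids <- function() {
  tibble(
    code1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
              "X", "*"),
    code3 = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val", "Xaa", "Ter")
  )
}

aa_order <- function() {
  aa <- amino_acids()
  c(sort(setdiff(aa$code3, c("Xaa", "Ter"))), "Xaa", "Ter")
}

code1_to_code3 <- function(x) {
  aa <- amino_acids()
  aa$code3[match(x, aa$code1)]
}

code3_lookup <- function(x) {
  aa <- amino_acids()
  # three-letter codes are matched case-insensitively (GLY, gly, Gly)
  aa$code3[match(paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3))),
                 aa$code3)]
}

#' Parse protein-change notation
#'
#' Classifies each protein-change string as a missense substitution, a
#' non-missense event, or unparseable. Accepted missense dialects:
#' `"p."`-prefixed or bare, parenthesized (`"p.(Gly661Arg)"`), three-letter
#' codes (case-insensitive) or strict uppercase one-letter codes. Frameshift
#' (`fs`), deletion, duplication, insertion, extension, synonymous (`=` or
#' identical residues) and stop-gain notations are classified
#' `not_missense` with a `subtype` saying which. Anything else, including
#' empty input, is `unparseable`. The function is total: no input errors.
#'
#' @param text Character vector of protein-change strings.
#' @return A tibble with one row per input: `input`, `status` (one of
#'   `"missense"`, `"not_missense"`, `"unparseable"`), `subtype`, `ref` and
#'   `alt` (three-letter codes, missense only), `position`, and `canonical`
#'   (the re-rendered `"p.Gly661Arg"` form, missense only).
#' @export
#' @examples
#' parse_protein_change(c("p.Gly661Arg", "G661R", "p.Gly661=", "p.Arg123fs"))
parse_protein_change <- function(text) {
  text <- as.character(text)
  n <- length(text)
  status <- rep("unparseable", n)
  subtype <- rep(NA_character_, n)
  ref <- rep(NA_character_, n)
  alt <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)

  body <- stringr::str_trim(text)
  body <- stringr::str_remove(body, stringr::regex("^p\\.", ignore_case = TRUE))
  body <- stringr::str_remove_all(body, "^\\(|\\)$")

  blank <- is.na(body) | body == ""

  # non-missense event notations, checked before substitution syntax
  event_pat <- c(
    frameshift = "fs",
    deletion = "del$",
    duplication = "dup$",
    insertion = "ins",
    deletion_insertion = "delins",
    extension = "ext"
  )
  for (ev in names(event_pat)) {
    hit <- !blank & status == "unparseable" &
      stringr::str_detect(body, stringr::regex(event_pat[[ev]], ignore_case = TRUE))
    status[hit] <- "not_missense"
    subtype[hit] <- ev
  }

  todo <- !blank & status == "unparseable"

  m3 <- stringr::str_match(body, "^([A-Za-z]{3})(\\d+)([A-Za-z]{3}|=|\\*)$")
  m1 <- stringr::str_match(body, "^([ARNDCQEGHILKMFPSTWYVX\\*])(\\d+)([ARNDCQEGHILKMFPSTWYVX\\*=])$")

  classify <- function(i, r3, a3, pos) {
    # r3/a3 canonical three-letter codes or NA; a3 == "=" means synonymous
    if (is.na(r3) || pos < 1) return()
    if (identical(a3, "=")) {
      status[i] <<- "not_missense"; subtype[i] <<- "synonymous"; return()
    }
    if (is.na(a3)) return()
    if (r3 == "Ter") {
      status[i] <<- "not_missense"; subtype[i] <<- "stop_lost"; return()
    }
    if (r3 == a3) {
      status[i] <<- "not_missense"; subtype[i] <<- "synonymous"; return()
    }
    if (a3 == "Ter") {
      status[i] <<- "not_missense"; subtype[i] <<- "stop_gain"
      ref[i] <<- r3; alt[i] <<- a3; position[i] <<- pos; return()
    }
    status[i] <<- "missense"; subtype[i] <<- "substitution"
    ref[i] <<- r3; alt[i] <<- a3; position[i] <<- pos
  }

  for (i in which(todo)) {
    if (!is.na(m3[i, 1])) {
      r3 <- code3_lookup(m3[i, 2])
      a_raw <- m3[i, 4]
      a3 <- if (a_raw == "=") "=" else if (a_raw == "*") "Ter" else code3_lookup(a_raw)
      classify(i, r3, a3, as.integer(m3[i, 3]))
    } else if (!is.na(m1[i, 1])) {
      r3 <- code1_to_code3(m1[i, 2])
      a_raw <- m1[i, 4]
      a3 <- if (a_raw == "=") "=" else code1_to_code3(a_raw)
      classify(i, r3, a3, as.integer(m1[i, 3]))
    }
  }

  tibble(
    input = text, status = status, subtype = subtype,
    ref = ref, position = position, alt = alt,
    canonical = dplyr::if_else(
      status == "missense",
      paste0("p.", ref, position, alt),
      NA_character_
    )
  )
}

#' Render a missense change in canonical notation
#'
#' @param ref,alt Three-letter residue codes.
#' @param position 1-based protein coordinate.
#' @return Character vector like `"p.Gly661Arg"`.
#' @export
render_protein_change <- function(ref, position, alt) {
  paste0("p.", ref, position, alt)
}

#' Build an amino-acid substitution matrix from variant records
#'
#' Counts reference-to-alternate residue substitutions over the records whose
#' `protein_change` parses to a missense change (and, optionally, stop
#' gains), one increment per record. The grand total of the matrix equals
#' the number of contributing records, and the diagonal is identically zero.
#'
#' @param records Variant tibble with `gene` and `protein_change` columns
#'   (as from [read_variant_table()]).
#' @param genes Optional character vector of gene symbols to restrict to
#'   (e.g. the collagen category of a catalog); `NULL` keeps all records.
#' @param include_stop_gain Count stop gains in the `Ter` column? Default
#'   `FALSE`: the matrix describes residue-for-residue substitution only.
#' @return An integer matrix of class `substitution_matrix` (rows =
#'   reference residue, columns = alternate, three-letter codes).
#' @export
substitution_matrix <- function(records, genes = NULL,
                                include_stop_gain = FALSE) {
  ord <- aa_order()
  m <- matrix(0L, nrow = length(ord), ncol = length(ord),
              dimnames = list(ref = ord, alt = ord))
  records <- as_tibble(records)
  if (nrow(records) > 0) {
    if (!is.null(genes)) records <- records[records$gene %in% genes, , drop = FALSE]
    parsed <- parse_protein_change(records$protein_change)
    keep <- parsed$status == "missense"
    if (include_stop_gain) {
      keep <- keep | (parsed$status == "not_missense" &
                        parsed$subtype %in% "stop_gain")
    }
    parsed <- parsed[keep, , drop = FALSE]
    if (nrow(parsed) > 0) {
      counts <- dplyr::count(parsed, .data$ref, .data$alt)
      m[cbind(counts$ref, counts$alt)] <- as.integer(counts$n)
    }
  }
  structure(m, class = c("substitution_matrix", class(m)))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  nz <- sum(x)
  cat("Amino-acid substitution matrix:", nz, "substitutions\n")
  keep_r <- rowSums(x) > 0
  keep_c <- colSums(x) > 0
  if (any(keep_r) && any(keep_c)) print(unclass(x)[keep_r, keep_c, drop = FALSE])
  invisible(x)
}

#' @export
tidy.substitution_matrix <- function(x, ...) {
  df <- as.data.frame.table(unclass(x), responseName = "n",
                            stringsAsFactors = FALSE)
  as_tibble(df[df$n > 0, c("ref", "alt", "n")])
}

#' Rank reference residues by substitution burden
#'
#' Row totals of a substitution matrix in descending order; ties broken
#' alphabetically by three-letter code so reports are reproducible.
#'
#' @param matrix A [substitution_matrix()].
#' @return A tibble `(ref, n)` sorted by descending count.
#' @export
rank_substituted <- function(matrix) {
  out <- tibble(ref = rownames(matrix), n = as.integer(rowSums(matrix)))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$ref)
}

#' Rank the substitution targets of one reference residue
#'
#' @param matrix A [substitution_matrix()].
#' @param ref Reference residue, one- or three-letter code.
#' @return A tibble `(alt, n)` sorted by descending count, ties alphabetical.
#' @export
rank_targets <- function(matrix, ref) {
  if (nchar(ref) == 1) ref <- code1_to_code3(ref)
  if (!ref %in% rownames(matrix)) {
    abort(paste0("unknown residue: ", ref), class = "ecm_domain_error")
  }
  out <- tibble(alt = colnames(matrix), n = as.integer(matrix[ref, ]))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$alt)
}

#' Position within the collagen Gly-X-Y repeat
#'
#' Collagen triple-helical domains repeat a Gly-X-Y triplet; a substitution's
#' position within the triplet determines whether it hits the obligatory
#' glycine slot. The slot is `((position - helix_start + offset) mod 3) + 1`.
#' Which slot carries the glycine is configurable (default slot 1, glycine
#' written first in the motif); the `offset` lets callers align a helix whose
#' first residue is not triplet-initial.
#'
#' @param position Protein coordinates (1-based), `>= helix_start`.
#' @param helix_start Coordinate of the first helical residue.
#' @param offset Frame offset in `{0, 1, 2}`.
#' @param glycine_slot Which triplet slot is the glycine position.
#' @return A tibble `(position, triplet_slot, is_glycine_slot)`.
#' @export
triplet_position <- function(position, helix_start = 1L, offset = 0L,
                             glycine_slot = 1L) {
  if (!offset %in% 0:2) abort("offset must be 0, 1 or 2", class = "ecm_domain_error")
  if (!glycine_slot %in% 1:3) abort("glycine_slot must be 1, 2 or 3",
                                    class = "ecm_domain_error")
  if (any(position < helix_start)) {
    abort("position precedes helix_start", class = "ecm_domain_error")
  }
  slot <- ((position - helix_start + offset) %% 3) + 1
  tibble(position = as.integer(position),
         triplet_slot = as.integer(slot),
         is_glycine_slot = slot == glycine_slot)
}

#' Count unique variants per disease
#'
#' Counts unique variant ids per normalized condition, sorted by descending
#' count (ties alphabetical). A variant id mapped to several diseases counts
#' once in each, so the column sum can exceed the number of unique ids.
#'
#' @param records Variant tibble (as from [read_variant_table()]).
#' @return A tibble `(disease, n_variants)` in descending order.
#' @export
variants_per_disease <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(disease = character(), n_variants = integer()))
  }
  disease <- if ("condition_norm" %in% names(records)) {
    records$condition_norm
  } else {
    normalize_disease(records$condition)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble(disease = disease, variant_id = records$variant_id),
                    .data$disease),
    n_variants = dplyr::n_distinct(.data$variant_id), .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$n_variants), .data$disease)
}
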