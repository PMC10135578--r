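# Small literature-derived fixtures in the canonical dialects: the collagen
# memberships of two classic collagenopathies, the plasminogen (PLG) drug
# panel, and the five-gene repurposing set. Gene, drug and SNP identifiers
# are the curated published ones; the disease indication names attached to
# the repurposing genes (beyond the defining syndromes) are synthetic
# placeholders, present only so that every fixture gene carries at least one
# association.

#' Collagen genes of two classic collagenopathies
#'
#' Stickler syndrome is the disease with the most associated collagens
#' (six); Ullrich congenital muscular dystrophy follows with four.
#'
#' @return A named list of two character vectors.
#' @export
collagenopathy_genes <- function() {
  list(
    stickler = c("COL2A1", "COL9A1", "COL9A2", "COL9A3", "COL11A1", "COL11A2"),
    ullrich = c("COL6A1", "COL6A2", "COL6A3", "COL12A1")
  )
}

#' The plasminogen drug panel
#'
#' The nine approved drugs targeting plasminogen (PLG, SNP rs783147), all
#' acting on the fibrinolysis axis.
#'
#' @return A character vector of nine drug names.
#' @export
plg_drugs <- function() {
  c("alteplase", "aminocaproic acid", "anistreplase", "aprotinin",
    "reteplase", "streptokinase", "tenecteplase", "tranexamic acid",
    "urokinase")
}

#' The five matrisome repurposing genes
#'
#' @return A character vector of five gene symbols.
#' @export
repurposing_genes <- function() {
  c("COL1A2", "NOV", "LPA", "MMP24", "PLG")
}

# sixteen synthetic indication names for the PLG candidate set
plg_indications <- function() {
  sprintf("thrombotic indication %02d", 1:16)
}

#' Write the literature-derived example fixtures
#'
#' Materializes the fixtures in the canonical dialects under `outdir`:
#' `stickler_associations.tsv` (6 collagen-disease rows),
#' `ullrich_associations.tsv` (4 rows), `plg_drugs.tsv` (9 drug-gene rows),
#' `repurposing_associations.tsv` (the five repurposing genes, PLG linked to
#' sixteen indications), and `fixture_matrisome.tsv`, a minimal catalog
#' covering every fixture gene.
#'
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_example_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cg <- collagenopathy_genes()
  stickler <- tibble(gene = cg$stickler, disease = "Stickler syndrome",
                     source = "monarch_like")
  ullrich <- tibble(gene = cg$ullrich,
                    disease = "Ullrich congenital muscular dystrophy",
                    source = "monarch_like")
  drugs <- tibble(drug = plg_drugs(), gene = "PLG", snp = "rs783147")
  repur <- dplyr::bind_rows(
    tibble(gene = "PLG", disease = plg_indications()),
    tibble(gene = c("COL1A2", "NOV", "LPA", "MMP24"),
           disease = c("osteogenesis imperfecta",
                       "synthetic indication nov",
                       "synthetic indication lpa",
                       "synthetic indication mmp24"))
  )
  repur$source <- "curated"
  collagens <- sort(unique(c(cg$stickler, cg$ullrich, "COL1A2", "COL3A1",
                             "COL4A5", "COL7A1")))
  catalog <- dplyr::bind_rows(
    tibble(symbol = collagens, category = "collagens"),
    tibble(symbol = "NOV", category = "glycoproteins"),
    tibble(symbol = c("LPA", "MMP24", "PLG"), category = "ecm_regulators")
  )
  catalog$division <- unname(DIVISION_FOR_CATEGORY[catalog$category])
  catalog <- catalog[, c("symbol", "division", "category")]

  files <- c(
    stickler = file.path(outdir, "stickler_associations.tsv"),
    ullrich = file.path(outdir, "ullrich_associations.tsv"),
    plg_drugs = file.path(outdir, "plg_drugs.tsv"),
    repurposing = file.path(outdir, "repurposing_associations.tsv"),
    catalog = file.path(outdir, "fixture_matrisome.tsv")
  )
  readr::write_tsv(stickler, files[["stickler"]], progress = FALSE)
  readr::write_tsv(ullrich, files[["ullrich"]], progress = FALSE)
  readr::write_tsv(drugs, files[["plg_drugs"]], progress = FALSE)
  readr::write_tsv(repur, files[["repurposing"]], progress = FALSE)
  readr::write_tsv(catalog, files[["catalog"]], progress = FALSE)
  invisible(files)
}
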