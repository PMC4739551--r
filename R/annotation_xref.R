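# Known/novel/intergenic classification, membership flags, hotspot flags,
# and the cross-reference link matrix to public databases.

#' Classify a variant as known, novel or intergenic
#'
#' Known iff a dbSNP rsID matches (position overlap, plus allele agreement
#' when the track carries alleles); novel iff no rsID but at least one gene
#' overlap; intergenic otherwise.
#'
#' @param nv a `normalized_variant`.
#' @param features data.frame from [assign_features()].
#' @param dbsnp_track an `interval_track` of rsID records (columns rsid and
#'   optionally ref/alt), or `NULL`.
#' @return list with `class` ("known", "novel" or "intergenic") and `rsid`
#'   (NA when unmatched).
#' @export
classify_variant <- function(nv, features, dbsnp_track = NULL) {
  rsid <- NA_character_
  if (!is.null(dbsnp_track)) {
    fp <- variant_footprint(nv)
    hits <- query_overlaps(dbsnp_track, nv$contig, fp[1], fp[2])
    if (nrow(hits) > 0) {
      has_alleles <- !is.na(hits$ref) & nzchar(hits$ref) &
                     !is.na(hits$alt) & nzchar(hits$alt)
      agree <- !has_alleles | (hits$ref == nv$ref & hits$alt == nv$alt)
      if (any(agree)) rsid <- hits$rsid[which(agree)[1]]
    }
  }
  genic <- any(features$region_class != "intergenic")
  cls <- if (!is.na(rsid)) "known" else if (genic) "novel" else "intergenic"
  list(class = cls, rsid = rsid)
}

MEMBERSHIP_TRACKS <- c("dbSnp_Common", "dbSnp_Coding", "Gwas_Catalogue",
                       "dbSnp_Flagged", "dbSnp_Mult", "dbSnp_HapMap",
                       "dbSnp_Cpg_Island")

#' Membership flags against dbSNP/GWAS subtracks
#'
#' One boolean per track; flagged when the variant footprint overlaps any
#' record of the track. Tracks absent from `tracks` report `FALSE`.
#'
#' @param nv a `normalized_variant`.
#' @param tracks named list of `interval_track`s (names from
#'   dbSnp_Common, dbSnp_Coding, Gwas_Catalogue, dbSnp_Flagged, dbSnp_Mult,
#'   dbSnp_HapMap, dbSnp_Cpg_Island).
#' @return named logical vector over the seven flag tracks.
#' @export
membership_flags <- function(nv, tracks) {
  fp <- variant_footprint(nv)
  vapply(MEMBERSHIP_TRACKS, function(nm) {
    tr <- tracks[[nm]]
    if (is.null(tr)) return(FALSE)
    nrow(query_overlaps(tr, nv$contig, fp[1], fp[2])) > 0
  }, logical(1))
}

#' Flag a variant overlapping a hotspot mutation
#'
#' @param nv a `normalized_variant`.
#' @param hotspots an `interval_track` from [load_hotspots()].
#' @return the name of the first overlapping hotspot (lexicographic
#'   tie-break), or `NA` when none overlaps.
#' @export
flag_hotspot <- function(nv, hotspots) {
  fp <- variant_footprint(nv)
  hits <- query_overlaps(hotspots, nv$contig, fp[1], fp[2])
  if (nrow(hits) == 0) return(NA_character_)
  sort(hits$name)[1]
}

#' The cross-reference link template matrix
#'
#' One row per annotation column of the summary table: the field name, the
#' identifier class that keys the link, a URL template, and the variant
#' classes (known / novel / intergenic) the link applies to. URL schemes
#' drift, so templates are configuration data: pass an edited copy to
#' [build_links()] to repoint a database.
#'
#' Placeholders: `{chrom}`, `{pos}`, `{rsid}`, `{entrez}`, `{symbol}`,
#' `{mrna}`, `{protein}`, `{uniprot}`, `{kegg}`, `{omim}`, `{hgnc}`.
#'
#' @return data.frame with columns field, key, template, known, novel,
#'   intergenic.
#' @export
link_templates <- function() {
  row <- function(field, key, template, known = TRUE, novel = FALSE,
                  intergenic = FALSE) {
    data.frame(field = field, key = key, template = template, known = known,
               novel = novel, intergenic = intergenic,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("Entrez_Gene", "entrez",
        "https://www.ncbi.nlm.nih.gov/gene/{entrez}", novel = TRUE),
    row("RefSeq_mRNA", "mrna",
        "https://www.ncbi.nlm.nih.gov/nuccore/{mrna}"),
    row("RefSeq_Protein", "protein",
        "https://www.ncbi.nlm.nih.gov/protein/{protein}"),
    row("HomoloGene", "mrna",
        "https://www.ncbi.nlm.nih.gov/homologene/?term={mrna}"),
    row("GEO_Profiles", "mrna",
        "https://www.ncbi.nlm.nih.gov/geoprofiles/?term={mrna}"),
    row("UniGene", "mrna",
        "https://www.ncbi.nlm.nih.gov/unigene/?term={mrna}"),
    row("Pubmed", "mrna",
        "https://pubmed.ncbi.nlm.nih.gov/?term={mrna}"),
    row("dbSNP", "rsid",
        "https://www.ncbi.nlm.nih.gov/snp/{rsid}", intergenic = TRUE),
    row("ClinVar", "entrez",
        "https://www.ncbi.nlm.nih.gov/clinvar/?term={entrez}%5Bgeneid%5D"),
    row("dbVar", "entrez",
        "https://www.ncbi.nlm.nih.gov/dbvar/?term={entrez}"),
    row("NCBI variation viewer", "rsid",
        "https://www.ncbi.nlm.nih.gov/variation/view/?q={rsid}",
        intergenic = TRUE),
    row("Cosmic", "symbol",
        "https://cancer.sanger.ac.uk/cosmic/gene/analysis?ln={symbol}"),
    row("Gen_Test_Reg", "entrez",
        "https://www.ncbi.nlm.nih.gov/gtr/all/tests/?term={entrez}"),
    row("Omim", "omim", "https://omim.org/entry/{omim}"),
    row("Hgnc", "hgnc",
        "https://www.genenames.org/data/gene-symbol-report/#!/hgnc_id/{hgnc}"),
    row("PolyPhen_2", "rsid",
        "http://genetics.bwh.harvard.edu/pph2/dbsearch.shtml?rsid={rsid}"),
    row("Decipher", "coord",
        "https://www.deciphergenomics.org/browser#q/{chrom}:{pos}-{pos}",
        novel = TRUE, intergenic = TRUE),
    row("Kegg", "kegg", "https://www.genome.jp/pathway/{kegg}"),
    row("Kegg_Locus", "kegg_entrez",
        "https://www.genome.jp/pathway/{kegg}+{entrez}"),
    row("Reactome", "uniprot",
        "https://reactome.org/content/query?q={uniprot}"),
    row("WikiGenes", "entrez",
        "https://www.wikigenes.org/e/gene/e/{entrez}.html", novel = TRUE),
    row("GeneTes", "symbol",
        "https://www.ncbi.nlm.nih.gov/gtr/genes/?term={symbol}"),
    row("BioGPS", "entrez",
        "http://biogps.org/#goto=genereport&id={entrez}", novel = TRUE),
    row("GENATLAS", "symbol",
        "http://genatlas.medecine.univ-paris5.fr/fiche.php?symbol={symbol}"),
    row("GeneCards", "symbol",
        "https://www.genecards.org/cgi-bin/carddisp.pl?gene={symbol}"),
    row("GOPubmed", "symbol",
        "https://gopubmed.org/search?q={symbol}"),
    row("H_InvDB", "symbol",
        "http://h-invitational.jp/hinv/spsoup/locus_search?query={symbol}"),
    row("UniProt", "uniprot",
        "https://www.uniprot.org/uniprotkb/{uniprot}"),
    row("QuickGO", "uniprot",
        "https://www.ebi.ac.uk/QuickGO/annotations?geneProductId={uniprot}"),
    row("UCSC", "coord",
        "https://genome.ucsc.edu/cgi-bin/hgTracks?position={chrom}:{pos}-{pos}",
        novel = TRUE, intergenic = TRUE),
    row("Ensembl", "coord",
        "https://www.ensembl.org/Homo_sapiens/Location/View?r={chrom}:{pos}-{pos}",
        novel = TRUE, intergenic = TRUE),
    row("GWAS_Central", "coord",
        "https://www.gwascentral.org/browser?q={chrom}:{pos}..{pos}",
        novel = TRUE, intergenic = TRUE)
  ))
}

#' Build database cross-reference links for a variant
#'
#' Emits one link per applicable template row: coordinate-keyed links for all
#' classes; rsID-keyed links for known (and intergenic, except PolyPhen-2);
#' Entrez-keyed gene links for known and novel; all remaining identifier
#' classes for known variants only. A builder whose identifier is missing is
#' skipped.
#'
#' @param identifiers list with any of `rsid`, `entrez`, `symbol`, `mrna`,
#'   `protein`, `uniprot`, `kegg`, `omim`, `hgnc`.
#' @param variant_class "known", "novel" or "intergenic".
#' @param contig contig name.
#' @param pos1 1-based variant position.
#' @param templates template matrix, defaults to [link_templates()].
#' @return data.frame with columns `field` and `url`; every URL contains its
#'   driving identifier verbatim.
#' @export
build_links <- function(identifiers, variant_class, contig, pos1,
                        templates = link_templates()) {
  variant_class <- match.arg(variant_class, c("known", "novel", "intergenic"))
  id <- function(k) {
    v <- identifiers[[k]]
    if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_ else as.character(v)
  }
  vals <- c(chrom = contig, pos = as.character(pos1),
            rsid = id("rsid"), entrez = id("entrez"), symbol = id("symbol"),
            mrna = id("mrna"), protein = id("protein"),
            uniprot = id("uniprot"), kegg = id("kegg"), omim = id("omim"),
            hgnc = id("hgnc"))
  rows <- templates[templates[[variant_class]], , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    key <- rows$key[i]
    need <- if (key == "coord") c("chrom", "pos")
            else if (key == "kegg_entrez") c("kegg", "entrez")
            else key
    if (any(is.na(vals[need]))) return(NULL)   # missing identifier: skip
    url <- rows$template[i]
    for (k in names(vals)) {
      if (!is.na(vals[[k]])) {
        url <- gsub(paste0("{", k, "}"), vals[[k]], url, fixed = TRUE)
      }
    }
    data.frame(field = rows$field[i], url = url, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(field = character(0), url = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
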