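# Reader/writer for the NUCOCOG-style XML dialect. The original database
# download does not document its schema, so the package defines (and
# documents) a minimal dialect:
#
#   <dataset source="cog|arcog|combined">
#     <organism id="..." name="..."/>
#     <cog id="COG0001" desc="...">
#       <seq org="..." protein_gi="..." gene_gi="...">
#         <aa>MKT...</aa>
#         <nt>ATGAAA...</nt>       <!-- optional: protein-only records -->
#       </seq>
#     </cog>
#   </dataset>
#
# Unknown attributes are ignored on read so that richer files still load.

#' Parse a NUCOCOG-style XML dataset
#'
#' Reads organisms, the COG catalogue and all member sequences from the XML
#' dialect described in the package vignette. Sequences are uppercased and
#' RNA-style `U` bases are normalized to `T` on read.
#'
#' @param path Path to the XML file.
#' @param source Which database flavour the file represents (`"cog"`,
#'   `"arcog"`, `"combined"`). Overridden by the file's own `source`
#'   attribute when present.
#' @return A [cog_dataset()].
#' @export
parse_nucocog_xml <- function(path, source = c("cog", "arcog", "combined")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop_parse(sprintf("malformed XML in '%s': %s",
                                           path, conditionMessage(e)))
  )
  file_source <- xml2::xml_attr(doc, "source")
  if (!is.na(file_source) && file_source %in% c("cog", "arcog", "combined")) {
    source <- file_source
  }

  org_nodes <- xml2::xml_find_all(doc, "./organism")
  organisms <- data.frame(
    organism_id = xml2::xml_attr(org_nodes, "id"),
    display_name = xml2::xml_attr(org_nodes, "name"),
    stringsAsFactors = FALSE
  )

  cog_nodes <- xml2::xml_find_all(doc, "./cog")
  cogs <- data.frame(
    cog_id = xml2::xml_attr(cog_nodes, "id"),
    description = ifelse(is.na(xml2::xml_attr(cog_nodes, "desc")), "",
                         xml2::xml_attr(cog_nodes, "desc")),
    stringsAsFactors = FALSE
  )

  # "./cog/seq" yields document order, so each sequence's COG is its parent's
  # id repeated per child count (xml_parent on a nodeset deduplicates).
  seq_nodes <- xml2::xml_find_all(doc, "./cog/seq")
  if (length(seq_nodes) == 0L) {
    stop_parse(sprintf("'%s' contains no sequence elements", path))
  }
  n_per_cog <- vapply(cog_nodes,
                      function(n) length(xml2::xml_find_all(n, "./seq")),
                      integer(1))
  seq_cog_id <- rep(cogs$cog_id, times = n_per_cog)
  aa <- xml2::xml_text(xml2::xml_find_first(seq_nodes, "./aa"))
  nt <- xml2::xml_text(xml2::xml_find_first(seq_nodes, "./nt"))
  nt[is.na(nt)] <- ""
  aa <- toupper(gsub("[[:space:]]", "", aa))
  nt <- gsub("U", "T", toupper(gsub("[[:space:]]", "", nt)), fixed = TRUE)

  sequences <- data.frame(
    organism_id = xml2::xml_attr(seq_nodes, "org"),
    cog_id = seq_cog_id,
    protein_gi = xml2::xml_attr(seq_nodes, "protein_gi"),
    gene_gi = xml2::xml_attr(seq_nodes, "gene_gi"),
    aa_seq = aa,
    nt_seq = nt,
    stringsAsFactors = FALSE
  )

  cog_dataset(source, organisms, cogs, sequences)
}

#' Write a dataset back to the XML dialect
#'
#' Text is assembled deterministically (fixed field order, fixed escaping),
#' so identical datasets produce byte-identical files; `parse_nucocog_xml()`
#' round-trips the result.
#'
#' @param ds A [cog_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nucocog_xml <- function(ds, path) {
  stopifnot(inherits(ds, "cog_dataset"))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<dataset source=\"%s\">", ds$source),
    sprintf("  <organism id=\"%s\" name=\"%s\"/>",
            xml_escape(ds$organisms$organism_id),
            xml_escape(ds$organisms$display_name))
  )
  seq_by_cog <- split(seq_len(nrow(ds$sequences)), ds$sequences$cog_id)
  for (k in seq_len(nrow(ds$cogs))) {
    cid <- ds$cogs$cog_id[k]
    out <- c(out, sprintf("  <cog id=\"%s\" desc=\"%s\">",
                          xml_escape(cid), xml_escape(ds$cogs$description[k])))
    for (i in seq_by_cog[[cid]]) {
      s <- ds$sequences[i, ]
      body <- sprintf("      <aa>%s</aa>", s$aa_seq)
      if (nzchar(s$nt_seq)) {
        body <- c(body, sprintf("      <nt>%s</nt>", s$nt_seq))
      }
      out <- c(out,
               sprintf("    <seq org=\"%s\" protein_gi=\"%s\" gene_gi=\"%s\">",
                       xml_escape(s$organism_id), xml_escape(s$protein_gi),
                       xml_escape(s$gene_gi)),
               body,
               "    </seq>")
    }
    out <- c(out, "  </cog>")
  }
  out <- c(out, "</dataset>")
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
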