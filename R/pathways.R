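#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated fields `name`,
#' `description`, then member gene ids. Members are de-duplicated per
#' pathway; duplicate pathway names are an error.
#'
#' @param path file path.
#' @return a `pathway_db`: list with `name`, `description` and `members`
#'   (list of character vectors), all parallel.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  name <- character(); desc <- character(); members <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d has %d fields, expected >= 3 (name, description, members)",
                   path, i, length(f)), call. = FALSE)
    if (f[1] %in% name)
      stop(sprintf("%s: duplicate pathway name '%s' at line %d", path, f[1], i),
           call. = FALSE)
    name <- c(name, f[1]); desc <- c(desc, f[2])
    members <- c(members, list(unique(f[-(1:2)])))
  }
  structure(list(name = name, description = desc, members = members),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db: %d pathways, median size %d>\n",
              length(x$name),
              if (length(x$name)) as.integer(median(lengths(x$members))) else 0L))
  invisible(x)
}

#' Score pathways by top-ranked membership
#'
#' For each gene set, the score is the number of its members ranked in
#' the top `top_n` of the gene ranking divided by the set's total size.
#' By default the denominator is the pathway's full membership, members
#' absent from the ranking universe included; set `restrict_universe =
#' TRUE` to use only members present in the ranking.
#'
#' @param ranking a [rank_genes()] result.
#' @param db a [read_gmt()] database.
#' @param top_n prefix size defining "top-ranked".
#' @param restrict_universe denominator choice (see above).
#' @return data.frame with columns `pathway`, `score`, `members_in_top`,
#'   `size`, sorted by decreasing score with ties broken by pathway name.
#' @export
pathway_scores <- function(ranking, db, top_n = 100L,
                           restrict_universe = FALSE) {
  stopifnot(inherits(db, "pathway_db"), top_n >= 1)
  top <- ranking$gene[ranking$rank <= top_n]
  universe <- ranking$gene
  rows <- lapply(seq_along(db$name), function(i) {
    mem <- db$members[[i]]
    size <- if (restrict_universe) sum(mem %in% universe) else length(mem)
    hits <- sum(mem %in% top)
    data.frame(pathway = db$name[i],
               score = if (size > 0) hits / size else 0,
               members_in_top = hits, size = size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$pathway, method = "radix"), , drop = FALSE]
}

#' Write pathway scores as TSV
#'
#' @param scores a [pathway_scores()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
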