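# Readers/writers for every external format the pipeline touches.
# All tables are plain TSV; FASTA goes through Biostrings.

#' Read a protein or CDS FASTA file
#'
#' Order is preserved, sequences are uppercased and `*` (stop) symbols are
#' retained. Duplicate identifiers are a hard error; an empty file yields an
#' empty record set with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `seq`, one row per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate id ", dup, " in ", path)
  }
  if (length(set) == 0L) warning("empty FASTA file: ", path)
  data.frame(id = ids, seq = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  lines <- character(0)
  if (nrow(records) > 0) {
    lines <- as.vector(rbind(paste0(">", records$id), records$seq))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-order table
#'
#' The table gives, per gene, its species, chromosome, integer rank along the
#' chromosome and strand. Ranks within each (species, chromosome) are
#' compacted to a gap-free `0..n-1` sequence preserving their original order,
#' so downstream windowed-synteny queries can use rank arithmetic directly.
#'
#' @param path TSV with columns `gene_id`, `species`, `chromosome`, `rank`,
#'   `strand`.
#' @return An object of class `gene_map`: a data.frame with the same columns,
#'   ranks re-indexed per chromosome.
#' @export
read_gene_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "species", "chromosome", "rank", "strand")
  if (!all(need %in% names(df))) {
    stop("gene map must have columns: ", paste(need, collapse = ", "))
  }
  df$rank <- as.integer(df$rank)
  gene_map(df)
}

#' Construct a gene_map from a data.frame
#'
#' @param df data.frame with `gene_id`, `species`, `chromosome`, `rank`,
#'   `strand`.
#' @return A `gene_map` object.
#' @export
gene_map <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene map: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  bad <- !(df$strand %in% c("+", "-", "unknown"))
  if (any(bad)) {
    warning("unknown strand symbol(s) stored as 'unknown'")
    df$strand[bad] <- "unknown"
  }
  key <- paste(df$species, df$chromosome, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- df$rank[idx]
    if (anyDuplicated(r)) {
      stop("duplicate rank on chromosome ", df$chromosome[idx[1L]],
           " of ", df$species[idx[1L]])
    }
    df$rank[idx[order(r)]] <- seq_along(idx) - 1L
  }
  df <- df[order(df$species, df$chromosome, df$rank), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_map", "data.frame"))
}

#' Write a gene_map as TSV
#' @param gm A `gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gm, path) {
  write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- orthology groups ------------------------------------------------------

#' Construct an orthology_groups object
#'
#' @param method_id Method label (e.g. `"mcl"`, `"rbh"`).
#' @param groups List of groups; each group is a named character vector of
#'   gene ids, names giving the species.
#' @return An `orthology_groups` object with a `gene -> group index` lookup.
#' @export
orthology_groups <- function(method_id, groups) {
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  genes <- unlist(lapply(groups, unname), use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("gene ", genes[duplicated(genes)][1L],
         " appears in more than one group for method ", method_id)
  }
  idx <- integer(0)
  if (length(groups) > 0) {
    idx <- rep(seq_along(groups), vapply(groups, length, 1L))
    names(idx) <- genes
  }
  structure(list(method_id = method_id, groups = groups, index = idx),
            class = "orthology_groups")
}

#' @export
print.orthology_groups <- function(x, ...) {
  cat("orthology_groups [", x$method_id, "]: ", length(x$groups),
      " groups, ", length(x$index), " genes\n", sep = "")
  invisible(x)
}

#' Group-mates of a gene
#'
#' @param og An `orthology_groups` object.
#' @param gene A gene id.
#' @param species Optional species filter for the returned mates.
#' @return Named character vector of group-mates (names = species), excluding
#'   the query gene; empty if the gene is in no group.
#' @export
group_mates <- function(og, gene, species = NULL) {
  gi <- og$index[gene]
  if (is.na(gi)) return(setNames(character(0), character(0)))
  g <- og$groups[[gi]]
  g <- g[g != gene]
  if (!is.null(species)) g <- g[names(g) %in% species]
  g
}

#' Read orthogroup predictions
#'
#' Two dialects are supported: `groups_text`, the OrthoMCL-style format
#' `GROUP1: spA|g1 spB|g2 ...`, and `pair_tsv`, a two-column TSV of pairwise
#' orthologue calls (`spA|geneA`, `spB|geneB`) which is closed into groups by
#' connected components; singleton components are dropped.
#'
#' @param path Input path.
#' @param dialect `"groups_text"` or `"pair_tsv"`.
#' @param method_id Label for the resulting object; default basename of path.
#' @param sep Species/gene separator (default `"|"`).
#' @return An [orthology_groups()] object.
#' @export
read_groups <- function(path, dialect = c("groups_text", "pair_tsv"),
                        method_id = NULL, sep = "|") {
  dialect <- match.arg(dialect)
  if (is.null(method_id)) method_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  split1 <- function(tok, lineno) {
    p <- strsplit(tok, sep, fixed = TRUE)[[1L]]
    if (length(p) != 2L || !nzchar(p[1L]) || !nzchar(p[2L])) {
      stop("malformed member '", tok, "' at line ", lineno, " of ", path)
    }
    p
  }
  if (dialect == "groups_text") {
    groups <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      m <- regmatches(lines[i], regexec("^\\s*(\\S+):\\s*(.*)$", lines[i]))[[1L]]
      if (length(m) != 3L) stop("malformed group line ", i, " of ", path)
      toks <- strsplit(trimws(m[3L]), "\\s+")[[1L]]
      parts <- vapply(toks, split1, character(2L), lineno = i)
      groups[[i]] <- setNames(parts[2L, ], parts[1L, ])
    }
    return(orthology_groups(method_id, groups))
  }
  # pair_tsv: close pairs into groups via graph connected components
  if (length(lines) == 0L) return(orthology_groups(method_id, list()))
  ab <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed pair at line ", i, " of ", path)
    c(f[1L], f[2L])
  })
  ab <- do.call(rbind, ab)
  verts <- unique(c(ab[, 1L], ab[, 2L]))
  g <- igraph::graph_from_edgelist(ab, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(members) {
    parts <- vapply(members, split1, character(2L), lineno = NA)
    setNames(parts[2L, ], parts[1L, ])
  })
  orthology_groups(method_id, unname(groups))
}

#' Write orthogroups in the groups-text dialect
#'
#' @param og An `orthology_groups` object.
#' @param path Output path.
#' @param sep Species/gene separator.
#' @return `path`, invisibly.
#' @export
write_groups <- function(og, path, sep = "|") {
  lines <- vapply(seq_along(og$groups), function(i) {
    g <- og$groups[[i]]
    paste0("GROUP", i, ": ",
           paste(paste(names(g), g, sep = sep), collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- domain hits -----------------------------------------------------------

#' Read a domain-hit table
#'
#' An hmmscan-domtblout-like TSV with one row per domain hit.
#'
#' @param path TSV with columns `gene_id`, `domain_name`, `start`, `end`,
#'   `score` (1-based inclusive amino-acid coordinates).
#' @return data.frame of validated hits.
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_name", "start", "end", "score")
  if (!all(need %in% names(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- as.numeric(df$score)
  if (any(df$start < 1L | df$end < df$start)) {
    stop("invalid domain coordinates (need 1 <= start <= end)")
  }
  df
}

#' Write a domain-hit table
#' @param hits data.frame of hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- expression ------------------------------------------------------------

#' Read a gene-by-tissue expression matrix
#'
#' The file is a TSV whose first column holds gene ids and whose header row
#' holds tissue labels from the canonical set `LE`, `F&P`, `S&S`, `RO`
#' (leaves; flowers & pollen; shoots & stems; roots). A `#platform:` comment
#' line may declare the platform; the `platform` argument overrides it.
#'
#' @param path Input TSV.
#' @param platform `"microarray"` or `"rnaseq"`; `NULL` to take it from the
#'   file header comment.
#' @return An `expression_matrix`: numeric matrix (genes x tissues) with a
#'   `platform` attribute.
#' @export
read_expression <- function(path, platform = NULL) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  if (is.null(platform)) {
    pl <- grep("^#platform:", lines, value = TRUE)
    if (length(pl) == 1L) platform <- trimws(sub("^#platform:", "", pl))
  }
  platform <- match.arg(platform, c("microarray", "rnaseq"))
  df <- read.delim(text = paste(lines[!is_comment], collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m, platform)
}

#' Construct an expression_matrix
#'
#' @param values Non-negative numeric matrix, genes in rows, tissues in
#'   columns named from `LE`, `F&P`, `S&S`, `RO`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, platform = c("microarray", "rnaseq")) {
  platform <- match.arg(platform)
  canonical <- c("LE", "F&P", "S&S", "RO")
  if (!all(colnames(values) %in% canonical)) {
    stop("tissue labels must be drawn from: ", paste(canonical, collapse = ", "))
  }
  storage.mode(values) <- "double"
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(values, platform = platform, class = c("expression_matrix", "matrix"))
}

#' Write an expression matrix as TSV
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#platform: ", attr(em, "platform")), con)
  df <- data.frame(gene_id = rownames(em), unclass(em), check.names = FALSE)
  # write.table quoting off keeps the F&P / S&S labels verbatim
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- factor inventory ------------------------------------------------------

#' Read a curated factor inventory
#'
#' One row per translocation factor: name, compartment, bait accessions
#' (semicolon-separated `species|gene_id` entries naming the experimentally
#' anchored genes used as search baits) and a literature flag.
#'
#' @param path TSV with columns `factor_name`, `compartment`, `baits`,
#'   `literature_flag`.
#' @return data.frame with a list-column `baits` of named character vectors
#'   (names = species).
#' @export
read_inventory <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("factor_name", "compartment", "baits", "literature_flag")
  if (!all(need %in% names(df))) {
    stop("inventory must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$factor_name)) {
    stop("duplicate factor_name: ", df$factor_name[duplicated(df$factor_name)][1L])
  }
  baits <- lapply(strsplit(df$baits, ";", fixed = TRUE), function(toks) {
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) stop("inventory row with no baits")
    parts <- do.call(rbind, strsplit(toks, "|", fixed = TRUE))
    setNames(parts[, 2L], parts[, 1L])
  })
  df$baits <- baits
  df
}

#' Write a factor inventory as TSV
#' @param inv Inventory data.frame as returned by [read_inventory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path) {
  out <- inv
  out$baits <- vapply(inv$baits, function(b) {
    paste(paste(names(b), b, sep = "|"), collapse = ";")
  }, character(1L))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 130-factor translocation inventory
#'
#' Loads the synthetic stand-in inventory bundled with the package: 130
#' curated protein translocation factors of the endoplasmic reticulum, ERAD,
#' peroxisomal, mitochondrial and chloroplast machineries of yeast and
#' Arabidopsis. Factor names and compartments follow the published
#' literature-based inventory; bait accessions are synthetic placeholders.
#'
#' @return Inventory data.frame (see [read_inventory()]).
#' @export
packaged_inventory <- function() {
  read_inventory(system.file("extdata", "factor_inventory_synthetic.tsv",
                             package = "coortho", mustWork = TRUE))
}
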