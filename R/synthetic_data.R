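# Genome-pair simulator with planted truth. Two proteomes descend from a
# common ancestor: lineage A undergoes two rounds of whole-genome duplication
# (the Arabidopsis-like history), lineage B one triplication (the
# Solanaceae-like history), with per-duplicate retention, gene loss, local
# rearrangement, gene fission (one gene annotated as two adjacent genes in
# one lineage), per-site sequence divergence, and four-tissue expression
# profiles with platform-specific scale factors and noise.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' 150 ancestral genes on 3 chromosomes, two WGD rounds with per-duplicate
#' retention 0.3 in lineage A, one triplication with retention 0.4 in
#' lineage B, gene-loss probability 0.1, substitution rate 0.05 per site,
#' 20 adjacent-transposition rearrangement ops, fission probability 0.02,
#' four tissues with lognormal profiles, and method-disagreement rate 0.18.
#'
#' @param n_ancestral_genes Number of ancestral genes.
#' @param n_chromosomes Ancestral chromosome count.
#' @param protein_length_range Ancestral protein lengths (aa), sampled
#'   uniformly.
#' @param domain_alphabet_size Number of distinct domain families.
#' @param architecture_length_range Domains per ancestral gene.
#' @param events_A,events_B Event lists per lineage; entries `"wgd"` or
#'   `"triplication"`.
#' @param retention_prob_A,retention_prob_B Per-duplicate retention
#'   probability for each lineage's duplication events.
#' @param loss_prob Per-gene loss probability applied after duplications.
#' @param rearrangement_ops Number of adjacent transpositions per lineage.
#' @param fission_prob Per-gene probability of being split into two adjacent
#'   annotations (architecture length >= 2 required).
#' @param substitution_rate Per-site substitution probability per lineage.
#' @param n_tissues Number of tissues (4; labels `LE`, `F&P`, `S&S`, `RO`).
#' @param profile_sd Log-scale SD of ancestral expression profiles.
#' @param noise_sd Log-scale SD of per-gene expression noise.
#' @param platform_scales Named scales, speciesA (microarray-like) and
#'   speciesB (RNA-seq-like).
#' @param method_disagreement_rate Probability that a group is perturbed in
#'   the second emulated method output.
#' @param n_factors Number of curated factors drawn from the ancestor.
#' @param seed Master seed; all sub-process streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ancestral_genes = 150,
                       n_chromosomes = 3,
                       protein_length_range = c(60, 160),
                       domain_alphabet_size = 30,
                       architecture_length_range = c(1, 4),
                       events_A = c("wgd", "wgd"),
                       events_B = c("triplication"),
                       retention_prob_A = 0.3,
                       retention_prob_B = 0.4,
                       loss_prob = 0.1,
                       rearrangement_ops = 20,
                       fission_prob = 0.02,
                       substitution_rate = 0.05,
                       n_tissues = 4,
                       profile_sd = 1,
                       noise_sd = 0.25,
                       platform_scales = c(spA = 100, spB = 1000),
                       method_disagreement_rate = 0.18,
                       n_factors = 40,
                       seed = 42) {
  stopifnot(loss_prob >= 0, loss_prob <= 1,
            retention_prob_A >= 0, retention_prob_A <= 1,
            retention_prob_B >= 0, retention_prob_B <= 1,
            fission_prob >= 0, fission_prob <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            seed == as.integer(seed), abs(seed) < 2^31 - 1000)
  structure(as.list(environment()), class = "sim_config")
}

tissue_labels <- function(n) c("LE", "F&P", "S&S", "RO")[seq_len(n)]

#' Simulate the ancestral genome
#'
#' Sequences are i.i.d. over the 20 amino acids at configured lengths;
#' architectures are drawn from the domain alphabet; genes get ranks
#' `0..n-1` distributed over the configured chromosomes; each gene gets a
#' lognormal base expression profile.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (data.frame `gene_id`, `chromosome`, `rank`,
#'   `seq`), `architectures` (named list) and `profiles` (matrix).
#' @export
simulate_ancestor <- function(config) {
  set.seed(config$seed)
  n <- config$n_ancestral_genes
  ids <- sprintf("anc%04d", seq_len(n))
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, "")
  alen <- sample(config$architecture_length_range[1]:
                 config$architecture_length_range[2], n, replace = TRUE)
  alphabet <- sprintf("DOM%02d", seq_len(config$domain_alphabet_size))
  archs <- lapply(alen, function(k) sample(alphabet, k, replace = TRUE))
  names(archs) <- ids
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(config$n_chromosomes)), n))
  rank <- unlist(lapply(split(seq_len(n), chrom), function(i) seq_along(i) - 1L),
                 use.names = FALSE)
  profiles <- matrix(exp(rnorm(n * config$n_tissues, mean = log(50),
                               sd = config$profile_sd)),
                     nrow = n,
                     dimnames = list(ids, tissue_labels(config$n_tissues)))
  list(genes = data.frame(gene_id = ids, chromosome = chrom, rank = rank,
                          seq = seqs, stringsAsFactors = FALSE),
       architectures = archs, profiles = profiles)
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Evolve one lineage from the ancestor
#'
#' Applies, in order: the duplication events (each whole chromosome is
#' duplicated onto a new mirror chromosome preserving gene order, and each
#' duplicate copy is retained with the lineage's retention probability; a
#' triplication adds two such mirrors), gene loss, gene fission, local
#' rearrangement by adjacent transpositions, and per-site substitution.
#' Every surviving gene records its ancestral source; fissions are logged
#' with both partner genes.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param events Character vector of `"wgd"` / `"triplication"`.
#' @param config A [sim_config()].
#' @param species Species tag used in gene ids (e.g. `"spA"`).
#' @param retention_prob Per-duplicate retention probability.
#' @param seed Stream seed for this lineage.
#' @return List with `genes` (data.frame `gene_id`, `ancestor`, `chromosome`,
#'   `rank`, `strand`, `seq`), `architectures`, and `fissions` (data.frame
#'   `ancestor`, `part1`, `part2`).
#' @export
evolve_lineage <- function(ancestor, events, config, species,
                           retention_prob, seed) {
  set.seed(seed)
  g <- ancestor$genes
  genes <- data.frame(gene_id = g$gene_id, ancestor = g$gene_id,
                      chromosome = g$chromosome, rank = g$rank,
                      seq = g$seq, stringsAsFactors = FALSE)
  archs <- ancestor$architectures
  copy_counter <- 0L
  for (ev in events) {
    n_copies <- switch(ev, wgd = 1L, triplication = 2L,
                       stop("unknown event: ", ev))
    base <- genes
    for (k in seq_len(n_copies)) {
      copy_counter <- copy_counter + 1L
      keep <- runif(nrow(base)) < retention_prob
      dup <- base[keep, , drop = FALSE]
      if (nrow(dup) == 0L) next
      new_ids <- paste0(dup$gene_id, "c", copy_counter)
      archs[new_ids] <- archs[dup$gene_id]
      dup$gene_id <- new_ids
      dup$chromosome <- paste0(dup$chromosome, "x", copy_counter)
      genes <- rbind(genes, dup)
    }
  }
  # loss
  lost <- runif(nrow(genes)) < config$loss_prob
  archs <- archs[setdiff(names(archs), genes$gene_id[lost])]
  genes <- genes[!lost, , drop = FALSE]
  # fission: split a gene with >= 2 domains into two adjacent annotations
  fiss <- data.frame(ancestor = character(0), part1 = character(0),
                     part2 = character(0), stringsAsFactors = FALSE)
  split_idx <- which(runif(nrow(genes)) < config$fission_prob &
                     lengths(archs[genes$gene_id]) >= 2L &
                     nchar(genes$seq) >= 20L)
  if (length(split_idx) > 0L) {
    extra <- genes[0, ]
    for (i in split_idx) {
      a <- archs[[genes$gene_id[i]]]
      cut_dom <- length(a) %/% 2L
      L <- nchar(genes$seq[i]); cut_aa <- L %/% 2L
      id1 <- paste0(genes$gene_id[i], "fa")
      id2 <- paste0(genes$gene_id[i], "fb")
      archs[[id1]] <- a[seq_len(cut_dom)]
      archs[[id2]] <- a[(cut_dom + 1L):length(a)]
      archs[[genes$gene_id[i]]] <- NULL
      row2 <- genes[i, ]
      row2$gene_id <- id2
      row2$seq <- substr(genes$seq[i], cut_aa + 1L, L)
      row2$rank <- genes$rank[i] + 0.5       # provisional; compacted below
      fiss <- rbind(fiss, data.frame(ancestor = genes$ancestor[i],
                                     part1 = id1, part2 = id2))
      genes$gene_id[i] <- id1
      genes$seq[i] <- substr(genes$seq[i], 1L, cut_aa)
      extra <- rbind(extra, row2)
    }
    genes <- rbind(genes, extra)
  }
  # compact ranks per chromosome (fission halves become adjacent)
  for (chr in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == chr)
    genes$rank[idx[order(genes$rank[idx])]] <- seq_along(idx) - 1L
  }
  genes$rank <- as.integer(genes$rank)
  # local rearrangement: adjacent transpositions
  chroms <- unique(genes$chromosome)
  for (op in seq_len(config$rearrangement_ops)) {
    chr <- sample(chroms, 1L)
    idx <- which(genes$chromosome == chr)
    if (length(idx) < 2L) next
    r <- sample(seq_len(length(idx) - 1L) - 1L, 1L)
    i1 <- idx[genes$rank[idx] == r]; i2 <- idx[genes$rank[idx] == r + 1L]
    genes$rank[i1] <- r + 1L; genes$rank[i2] <- r
  }
  # divergence
  genes$seq <- vapply(genes$seq, mutate_seq, "",
                      rate = config$substitution_rate, USE.NAMES = FALSE)
  # species-tagged ids
  new_id <- paste0(species, "_", genes$gene_id)
  names(archs)[match(genes$gene_id, names(archs))] <- new_id
  if (nrow(fiss) > 0L) {
    fiss$part1 <- paste0(species, "_", fiss$part1)
    fiss$part2 <- paste0(species, "_", fiss$part2)
  }
  genes$gene_id <- new_id
  genes$strand <- "+"
  genes <- genes[order(genes$chromosome, genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, architectures = archs[genes$gene_id], fissions = fiss)
}

#' Emulate the outputs of two orthogroup prediction methods
#'
#' Method 1 reproduces the planted groups exactly. Method 2 perturbs each
#' group independently with probability `d`: a perturbed group either drops a
#' random member or exchanges a random member with another perturbed group,
#' so unperturbed groups are never touched and the fraction of disagreeing
#' groups is binomial with rate `d`.
#'
#' @param planted_groups List of groups (named character vectors,
#'   names = species).
#' @param d Disagreement rate in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `method1`, `method2` ([orthology_groups()]) and
#'   `perturbed` (logical vector over the planted groups).
#' @export
emulate_method_outputs <- function(planted_groups, d, seed) {
  set.seed(seed)
  groups2 <- planted_groups
  n <- length(planted_groups)
  perturbed <- runif(n) < d
  action <- ifelse(runif(n) < 0.5, "drop", "swap")
  swappers <- which(perturbed & action == "swap")
  # pair up exchange partners; an unpaired swapper falls back to a drop
  if (length(swappers) %% 2L == 1L) {
    action[swappers[length(swappers)]] <- "drop"
    swappers <- swappers[-length(swappers)]
  }
  for (i in which(perturbed & action == "drop")) {
    g <- groups2[[i]]
    victim <- sample(length(g), 1L)
    groups2[[i]] <- g[-victim]
  }
  if (length(swappers) >= 2L) {
    for (k in seq(1L, length(swappers) - 1L, by = 2L)) {
      i <- swappers[k]; j <- swappers[k + 1L]
      gi <- groups2[[i]]; gj <- groups2[[j]]
      vi <- sample(length(gi), 1L); vj <- sample(length(gj), 1L)
      moved_i <- gi[vi]; moved_j <- gj[vj]
      groups2[[i]] <- c(gi[-vi], moved_j)
      groups2[[j]] <- c(gj[-vj], moved_i)
    }
  }
  list(method1 = orthology_groups("method1", planted_groups),
       method2 = orthology_groups("method2", groups2),
       perturbed = perturbed)
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Runs the ancestor simulation and both lineage histories, then assembles
#' every input the pipeline reads: protein records and CDS lengths for both
#' species, a joint gene map, a domain-hit table, two emulated orthogroup
#' predictions, per-species expression matrices, and a factor inventory whose
#' baits are lineage-A genes. The truth table records planted orthologue
#' pairs, planted groups, fission (split-gene) events and the factor-bait
#' mapping.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `proteins`, `cds`,
#'   `gene_map`, `domain_table`, `groups` (list of two [orthology_groups()]),
#'   `expression` (list `spA`, `spB`), `inventory`, `truth`, `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  anc <- simulate_ancestor(config)
  linA <- evolve_lineage(anc, config$events_A, config, "spA",
                         config$retention_prob_A, seed = config$seed + 1L)
  linB <- evolve_lineage(anc, config$events_B, config, "spB",
                         config$retention_prob_B, seed = config$seed + 2L)
  genes <- rbind(cbind(linA$genes, species = "spA"),
                 cbind(linB$genes, species = "spB"))
  proteins <- data.frame(id = genes$gene_id, seq = genes$seq,
                         species = genes$species, stringsAsFactors = FALSE)
  cds <- data.frame(id = genes$gene_id,
                    cds_length = 3L * (nchar(genes$seq) + 1L))
  gmap <- gene_map(data.frame(gene_id = genes$gene_id,
                              species = genes$species,
                              chromosome = genes$chromosome,
                              rank = genes$rank, strand = genes$strand,
                              stringsAsFactors = FALSE))
  archs <- c(linA$architectures, linB$architectures)
  domain_table <- synthesize_domain_hits(proteins, archs,
                                         seed = config$seed + 3L)
  # planted groups: all surviving descendants of one ancestral gene
  species_of <- setNames(genes$species, genes$gene_id)
  by_anc <- split(genes$gene_id, genes$ancestor)
  planted_groups <- lapply(by_anc, function(members) {
    members <- sort(members)
    setNames(members, unname(species_of[members]))
  })
  pairs <- do.call(rbind, lapply(names(by_anc), function(a) {
    ga <- sort(genes$gene_id[genes$ancestor == a & genes$species == "spA"])
    gb <- sort(genes$gene_id[genes$ancestor == a & genes$species == "spB"])
    if (length(ga) == 0L || length(gb) == 0L) return(NULL)
    rel <- if (length(ga) == 1L && length(gb) == 1L) "one2one" else "co_orthologue"
    data.frame(ancestor = a, geneA = rep(ga, each = length(gb)),
               geneB = rep(gb, times = length(ga)), relation = rel,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(ancestor = character(0), geneA = character(0),
                        geneB = character(0), relation = character(0))
  }
  emul <- emulate_method_outputs(unname(planted_groups),
                                 d = config$method_disagreement_rate,
                                 seed = config$seed + 4L)
  # factor inventory: ancestors with a surviving lineage-A descendant as bait
  set.seed(config$seed + 5L)
  eligible <- names(by_anc)[vapply(names(by_anc), function(a) {
    any(genes$ancestor == a & genes$species == "spA")
  }, TRUE)]
  fac_anc <- sort(sample(eligible, min(config$n_factors, length(eligible))))
  baits <- vapply(fac_anc, function(a) {
    sort(genes$gene_id[genes$ancestor == a & genes$species == "spA"])[1L]
  }, "")
  inventory <- data.frame(factor_name = sprintf("factor_%s", fac_anc),
                          compartment = "synthetic",
                          literature_flag = "synthetic",
                          stringsAsFactors = FALSE)
  inventory$baits <- lapply(baits, function(b) setNames(b, "spA"))
  # expression: descendants inherit the ancestral profile plus lognormal noise
  set.seed(config$seed + 6L)
  expr <- lapply(c(spA = "spA", spB = "spB"), function(sp) {
    ids <- genes$gene_id[genes$species == sp]
    base <- anc$profiles[species_of_ancestor(ids, genes), , drop = FALSE]
    noise <- matrix(exp(rnorm(length(base), sd = config$noise_sd)),
                    nrow = nrow(base))
    m <- base * noise
    rownames(m) <- ids
    expression_matrix(m, if (sp == "spA") "microarray" else "rnaseq")
  })
  truth <- list(pairs = pairs, groups = planted_groups,
                fusions = rbind(linA$fissions, linB$fissions),
                factor_baits = setNames(unname(baits), inventory$factor_name),
                perturbed = emul$perturbed)
  structure(list(proteins = proteins, cds = cds, gene_map = gmap,
                 domain_table = domain_table, architectures = archs,
                 groups = list(method1 = emul$method1,
                               method2 = emul$method2),
                 expression = expr, inventory = inventory, truth = truth,
                 config = config),
            class = "sim_dataset")
}

species_of_ancestor <- function(ids, genes) {
  genes$ancestor[match(ids, genes$gene_id)]
}

# deterministic domain-hit coordinates: pack the architecture into the
# protein, leaving a 1-residue gap between consecutive domains
synthesize_domain_hits <- function(proteins, archs, seed) {
  set.seed(seed)
  rows <- lapply(proteins$id, function(id) {
    a <- archs[[id]]
    if (is.null(a) || length(a) == 0L) return(NULL)
    L <- nchar(proteins$seq[proteins$id == id])
    seg <- max(2L, L %/% length(a))
    start <- pmin((seq_along(a) - 1L) * seg + 1L, L)
    end <- pmin(start + seg - 2L, L)
    end <- pmax(end, start)
    data.frame(gene_id = id, domain_name = a, start = start, end = end,
               score = round(runif(length(a), 25, 60), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes every file of the standard input bundle plus the truth tables, so
#' the on-disk readers can be exercised against generated data.
#'
#' @param ds A `sim_dataset` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  for (sp in unique(ds$proteins$species)) {
    sub <- ds$proteins[ds$proteins$species == sp, c("id", "seq")]
    write_fasta(sub, p(paste0(sp, "_proteins.fasta")))
  }
  write.table(ds$cds, p("cds_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gene_map(ds$gene_map, p("gene_map.tsv"))
  write_domain_table(ds$domain_table, p("domain_hits.tsv"))
  write_groups(ds$groups$method1, p("groups_method1.txt"))
  write_groups(ds$groups$method2, p("groups_method2.txt"))
  for (sp in names(ds$expression)) {
    write_expression(ds$expression[[sp]], p(paste0(sp, "_expression.tsv")))
  }
  write_inventory(ds$inventory, p("inventory.tsv"))
  write.table(ds$truth$pairs, p("truth_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$fusions, p("truth_fusions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(paste0("seed: ", ds$config$seed), p("seed.txt"))
  invisible(dir)
}
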