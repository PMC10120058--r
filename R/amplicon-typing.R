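## TSR codon typing and origin counting on amplicon haplotypes.

# 1-letter -> 3-letter amino-acid codes
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          `*` = "Ter")

#' Default TSR codon tables
#'
#' Known target-site resistance codons: ACCase 1781 (Ile -> Leu/Thr/Val),
#' 1999 (Trp -> Leu), 2027 (Trp -> Cys), 2041 (Ile -> Asn), 2078
#' (Asp -> Gly); ALS1 197 (Pro -> Thr/Ala/Ser) and 574 (Trp -> Leu). The
#' `pos` column holds the 1-based coordinate of the codon's first
#' nucleotide on the *bundled mock reference* (see [mockReference()]),
#' which carries the real reference codons at scaled coordinates; when
#' typing real amplicons supply a table with annotation-derived
#' coordinates (see [readCodonTable()]).
#'
#' @param gene `"ACCase"` or `"ALS1"`.
#' @return data.frame with columns `gene`, `codon`, `ref_aa`, `res_aa`
#'   (comma-separated 3-letter codes) and `pos`.
#' @export
tsrCodonTable <- function(gene = c("ACCase", "ALS1")) {
  gene <- match.arg(gene)
  if (gene == "ACCase")
    data.frame(gene = "ACCase",
               codon = c(1781L, 1999L, 2027L, 2041L, 2078L),
               ref_aa = c("Ile", "Trp", "Trp", "Ile", "Asp"),
               res_aa = c("Leu,Thr,Val", "Leu", "Cys", "Asn", "Gly"),
               pos = c(301L, 601L, 901L, 1201L, 1501L))
  else
    data.frame(gene = "ALS1",
               codon = c(197L, 574L),
               ref_aa = c("Pro", "Trp"),
               res_aa = c("Thr,Ala,Ser", "Leu"),
               pos = c(401L, 1101L))
}

# reference codons used by the mock references
.REF_CODON <- c(Ile = "ATA", Trp = "TGG", Asp = "GAT", Pro = "CCT")

#' Bundled mock reference sequences
#'
#' Deterministic 2,001-bp synthetic reference per gene carrying the real
#' TSR reference codons (Ile/Trp/Trp/Ile/Asp for ACCase; Pro/Trp for ALS1)
#' at the scaled coordinates of [tsrCodonTable()], so codon anchoring and
#' translation logic can be exercised without shipping the true 13.2-kb
#' amplicon. Synthetic stand-in: not the real gene sequence.
#'
#' @param gene `"ACCase"` or `"ALS1"`.
#' @return a [Biostrings::DNAString].
#' @export
mockReference <- function(gene = c("ACCase", "ALS1")) {
  gene <- match.arg(gene)
  L <- 2001L
  seedByGene <- c(ACCase = 20270L, ALS1 = 19700L)
  base <- .withSeed(seedByGene[[gene]],
                    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  tab <- tsrCodonTable(gene)
  for (i in seq_len(nrow(tab))) {
    codon <- strsplit(.REF_CODON[[tab$ref_aa[i]]], "")[[1]]
    base[tab$pos[i] + 0:2] <- codon
  }
  Biostrings::DNAString(paste(base, collapse = ""))
}

#' Read / write a TSR codon table as JSON
#'
#' JSON layout: `{"gene": ..., "codons": [{"codon": 1781, "ref_aa": "Ile",
#' "res_aa": ["Leu", ...], "pos": [p1, p2, p3] | p}, ...]}`.
#'
#' @param path JSON file path.
#' @return data.frame in the [tsrCodonTable()] layout.
#' @export
readCodonTable <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cod <- js$codons
  res <- vapply(cod$res_aa, function(x) paste(unlist(x), collapse = ","),
                character(1))
  pos <- vapply(cod$pos, function(x) as.integer(unlist(x)[1]), integer(1))
  data.frame(gene = js$gene, codon = as.integer(cod$codon),
             ref_aa = cod$ref_aa, res_aa = unname(res), pos = pos)
}

#' @rdname readCodonTable
#' @param table codon table data.frame.
#' @export
writeCodonTable <- function(table, path) {
  js <- list(gene = unique(table$gene),
             codons = lapply(seq_len(nrow(table)), function(i)
               list(codon = table$codon[i], ref_aa = table$ref_aa[i],
                    res_aa = strsplit(table$res_aa[i], ",")[[1]],
                    pos = table$pos[i])))
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read amplicon haplotypes with the header convention
#'
#' FASTA headers follow `sampleID|populationID|gene|phase`; the parsed
#' fields are attached as metadata columns.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] with `mcols` columns `sample_id`,
#'   `population_id`, `gene`, `phase`.
#' @export
readAmpliconFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("headers must follow sampleID|populationID|gene|phase")
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    sample_id = vapply(parts, `[`, "", 1L),
    population_id = vapply(parts, `[`, "", 2L),
    gene = vapply(parts, `[`, "", 3L),
    phase = vapply(parts, `[`, "", 4L))
  x
}

# map reference coordinates to haplotype bases; fast path for ungapped
# equal-length input, otherwise a global pairwise alignment anchors the
# haplotype to the reference
.codonBases <- function(hap, reference, positions) {
  hs <- toupper(as.character(hap))
  rs <- toupper(as.character(reference))
  if (nchar(hs) == nchar(rs) && !grepl("-", hs, fixed = TRUE)) {
    return(vapply(positions, function(p) substr(hs, p, p), character(1)))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(gsub("-", "", hs)),
    subject = reference, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refCol <- cumsum(sa != "-")  # alignment column -> reference coordinate
  vapply(positions, function(p) {
    col <- match(p, refCol)
    if (is.na(col)) "-" else pa[col]
  }, character(1))
}

#' Call TSR codon substitutions on amplicon haplotypes
#'
#' Anchors each haplotype to the reference, translates every codon listed
#' in the codon table, and labels codons whose amino acid falls in the
#' resistant set. Codons with gaps or ambiguous bases are reported as
#' `uncallable` (never silently wild type).
#'
#' @param haps a [Biostrings::DNAStringSet] (or single `DNAString`).
#' @param gene gene name, used for the default table and reference.
#' @param table codon table ([tsrCodonTable()] layout).
#' @param reference reference sequence the table coordinates refer to.
#' @return data.frame with one row per haplotype x codon: `hap` (name or
#'   index), `gene`, `codon`, `observed_aa`, `status`
#'   (`wild_type`/`resistant`/`uncallable`) and `label` (e.g.
#'   `"ACCase Ile1781Leu"`, `NA` unless resistant).
#' @examples
#' ref <- mockReference("ACCase")
#' calls <- callTSR(Biostrings::DNAStringSet(ref), "ACCase")
#' subset(calls, status == "resistant")  # none on the reference itself
#' @export
callTSR <- function(haps, gene = c("ACCase", "ALS1"),
                    table = tsrCodonTable(gene),
                    reference = mockReference(gene)) {
  gene <- match.arg(gene)
  if (is(haps, "DNAString")) haps <- Biostrings::DNAStringSet(haps)
  nm <- names(haps)
  if (is.null(nm)) nm <- as.character(seq_along(haps))
  gc <- Biostrings::GENETIC_CODE
  out <- vector("list", length(haps))
  for (i in seq_along(haps)) {
    pos <- unlist(lapply(table$pos, function(p) p + 0:2))
    bases <- .codonBases(haps[[i]], reference, pos)
    rows <- lapply(seq_len(nrow(table)), function(k) {
      cod <- bases[(3 * (k - 1) + 1):(3 * k)]
      codon <- paste(cod, collapse = "")
      if (!grepl("^[ACGT]{3}$", codon)) {
        return(data.frame(hap = nm[i], gene = gene,
                          codon = table$codon[k],
                          observed_aa = NA_character_,
                          status = "uncallable", label = NA_character_))
      }
      aa <- .AA3[[gc[[codon]]]]
      resSet <- strsplit(table$res_aa[k], ",")[[1]]
      if (aa %in% resSet) {
        lab <- paste0(gene, " ", table$ref_aa[k], table$codon[k], aa)
        data.frame(hap = nm[i], gene = gene, codon = table$codon[k],
                   observed_aa = aa, status = "resistant", label = lab)
      } else {
        data.frame(hap = nm[i], gene = gene, codon = table$codon[k],
                   observed_aa = aa, status = "wild_type",
                   label = NA_character_)
      }
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Deduplicate amplicon haplotypes into nonredundant clusters
#'
#' Exact-sequence grouping after uppercasing and gap removal. Each cluster
#' is annotated with its member count, populations of occurrence and
#' whether it is shared (observed in two or more populations). If a codon
#' `table` and `reference` are supplied the representative of each
#' cluster is TSR-typed.
#'
#' @param haps a [Biostrings::DNAStringSet]; population labels are taken
#'   from `populations` or from `mcols(haps)$population_id`.
#' @param populations optional character vector of population labels.
#' @param gene optional gene check: mixed-gene input is rejected when
#'   `mcols(haps)$gene` is present.
#' @param table,reference optional TSR annotation inputs (see
#'   [callTSR()]).
#' @return data.frame with one row per nonredundant haplotype: `cluster`,
#'   `count`, `populations`, `n_populations`, `shared`, `representative`
#'   (index into `haps`) and, when annotated, `tsr` + `tsr_labels`.
#' @export
dedupeHaplotypes <- function(haps, populations = NULL, gene = NULL,
                             table = NULL, reference = NULL) {
  meta <- S4Vectors::mcols(haps)
  if (!is.null(meta) && "gene" %in% names(meta)) {
    genes <- unique(meta$gene)
    if (length(genes) > 1L)
      stop("mixed genes in input: ", paste(genes, collapse = ", "))
    if (is.null(gene)) gene <- genes
  }
  if (is.null(populations)) {
    populations <- if (!is.null(meta) && "population_id" %in% names(meta))
      meta$population_id else rep("pop1", length(haps))
  }
  seqs <- gsub("-", "", toupper(as.character(haps)), fixed = TRUE)
  grp <- match(seqs, unique(seqs))
  ord <- unique(grp)
  rows <- lapply(ord, function(g) {
    members <- which(grp == g)
    pops <- sort(unique(populations[members]))
    data.frame(cluster = paste0("H", g), count = length(members),
               populations = paste(pops, collapse = ","),
               n_populations = length(pops),
               shared = length(pops) >= 2L,
               representative = members[1L])
  })
  res <- do.call(rbind, rows)
  if (!is.null(table) || !is.null(reference) || !is.null(gene)) {
    gene <- gene %||% "ACCase"
    if (is.null(table)) table <- tsrCodonTable(gene)
    if (is.null(reference)) reference <- mockReference(gene)
    calls <- callTSR(haps[res$representative], gene = gene, table = table,
                     reference = reference)
    calls$repIndex <- rep(seq_len(nrow(res)), each = nrow(table))
    res$tsr <- vapply(seq_len(nrow(res)), function(i)
      any(calls$status[calls$repIndex == i] == "resistant"), logical(1))
    res$tsr_labels <- vapply(seq_len(nrow(res)), function(i) {
      lab <- calls$label[calls$repIndex == i & calls$status == "resistant"]
      paste(lab, collapse = ",")
    }, character(1))
  }
  res
}

#' Shared-versus-private 2x2 table of nonredundant haplotypes
#'
#' Cross-tabulates TSR status against sharing across populations:
#' rows (TSR, wild type), columns (shared, private). Feeds
#' [chi2Yates()].
#'
#' @param clusters deduplicated clusters from [dedupeHaplotypes()] with a
#'   `tsr` column.
#' @return 2x2 integer matrix.
#' @export
shared2x2 <- function(clusters) {
  if (!all(c("tsr", "shared") %in% names(clusters)))
    stop("clusters need 'tsr' and 'shared' columns ",
         "(run dedupeHaplotypes with a codon table)")
  m <- matrix(c(sum(clusters$tsr & clusters$shared),
                sum(clusters$tsr & !clusters$shared),
                sum(!clusters$tsr & clusters$shared),
                sum(!clusters$tsr & !clusters$shared)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("TSR", "wild_type"),
                              c("shared", "private")))
  m
}

# first index at which a differs from b (Inf if identical)
.firstMismatch <- function(a, b) {
  d <- which(a != b)
  if (length(d)) d[1L] else Inf
}
.lastMismatch <- function(a, b) {
  d <- which(a != b)
  if (length(d)) d[length(d)] else 0L
}

#' Count independent TSR origins within a field population
#'
#' For each TSR mutation observed in a single population, carriers are
#' grouped into haplotype backbones (sequences compared with the mutated
#' codon masked; single-linkage, two sequences belong to the same backbone
#' when they differ at `kBackbone` or fewer sites). A distinct backbone is
#' downgraded to `putative_recombinant` when its sequence can be written
#' exactly as a single-breakpoint mosaic of one observed TSR haplotype
#' (from another backbone) and one observed wild-type haplotype; remaining
#' backbones are `independent_origin`. Input sequences must be aligned to
#' equal length.
#'
#' @param haps a [Biostrings::DNAStringSet] from one population and gene.
#' @param gene gene name.
#' @param table,reference see [callTSR()].
#' @param kBackbone backbone-distinctness threshold (default 3 differing
#'   sites, guarding against sequencing noise).
#' @return list of class `"OriginCallReport"`: `per_mutation` data.frame
#'   (`mutation`, `backbone`, `n_haplotypes`, `call`, `breakpoint_lo`,
#'   `breakpoint_hi`), `n_independent` per mutation, and
#'   `total_independent` for the field.
#' @export
countOrigins <- function(haps, gene = c("ACCase", "ALS1"),
                         table = tsrCodonTable(gene),
                         reference = mockReference(gene), kBackbone = 3L) {
  gene <- match.arg(gene)
  meta <- S4Vectors::mcols(haps)
  if (!is.null(meta) && "population_id" %in% names(meta) &&
      length(unique(meta$population_id)) > 1L)
    stop("countOrigins expects haplotypes from a single population")
  if (length(unique(Biostrings::width(haps))) != 1L)
    stop("sequences must be aligned to equal length")
  calls <- callTSR(haps, gene = gene, table = table,
                   reference = reference)
  idx <- rep(seq_along(haps), each = nrow(table))
  chars <- strsplit(toupper(as.character(haps)), "")
  isRes <- tapply(calls$status == "resistant", idx, any)
  wtPool <- which(!isRes)

  labels <- unique(stats::na.omit(calls$label))
  perMut <- list()
  nIndep <- integer(0)
  for (lab in labels) {
    rows <- calls$label == lab & !is.na(calls$label)
    carriers <- unique(idx[rows])
    codonRow <- match(calls$codon[rows][1L], table$codon)
    mask <- table$pos[codonRow] + 0:2
    # backbone clustering on masked sequences, single linkage
    d <- function(i, j) {
      a <- chars[[i]]; b <- chars[[j]]
      sum(a[-mask] != b[-mask])
    }
    comp <- seq_along(carriers)
    for (i in seq_along(carriers))
      for (j in seq_len(i - 1L))
        if (d(carriers[i], carriers[j]) <= kBackbone) {
          old <- comp[i]; comp[comp == old] <- comp[j]
        }
    groups <- split(carriers, comp)
    # largest backbone first; it is never downgraded, so at least one
    # independent origin is reported whenever the mutation is observed
    groups <- groups[order(-lengths(groups))]
    # point-mutation parsimony: a carrier whose backbone matches an
    # observed wild-type haplotype (masked distance <= kBackbone) is a
    # single mutational step away from it, which beats any recombination
    # explanation
    onWtBackbone <- vapply(groups, function(members) {
      cand <- chars[[members[1L]]]
      any(vapply(wtPool, function(w)
        sum(cand[-mask] != chars[[w]][-mask]) <= kBackbone, logical(1)))
    }, logical(1))
    callsOut <- lapply(seq_along(groups), function(g) {
      members <- groups[[g]]
      cand <- chars[[members[1L]]]
      partners <- if (g == 1L || onWtBackbone[g]) integer() else
        setdiff(unlist(groups[-g]), members)
      bpLo <- NA_integer_; bpHi <- NA_integer_
      isRec <- FALSE
      for (t in partners) {
        for (w in wtPool) {
          tc <- chars[[t]]; wc <- chars[[w]]
          # orientation 1: [1..b) from t, [b..L] from w
          f <- .firstMismatch(cand, tc); l <- .lastMismatch(cand, wc)
          if (l < f) {
            isRec <- TRUE; bpLo <- as.integer(l) + 1L
            bpHi <- as.integer(min(f, length(cand)))
            break
          }
          # orientation 2: [1..b) from w, [b..L] from t
          f2 <- .lastMismatch(cand, tc); l2 <- .firstMismatch(cand, wc)
          if (f2 < l2) {
            isRec <- TRUE; bpLo <- as.integer(f2) + 1L
            bpHi <- as.integer(min(l2, length(cand)))
            break
          }
        }
        if (isRec) break
      }
      data.frame(mutation = lab, backbone = g,
                 n_haplotypes = length(members),
                 call = if (isRec) "putative_recombinant"
                        else "independent_origin",
                 breakpoint_lo = bpLo, breakpoint_hi = bpHi)
    })
    tab <- do.call(rbind, callsOut)
    perMut[[lab]] <- tab
    nIndep[lab] <- sum(tab$call == "independent_origin")
  }
  per <- if (length(perMut)) do.call(rbind, perMut) else
    data.frame(mutation = character(), backbone = integer(),
               n_haplotypes = integer(), call = character(),
               breakpoint_lo = integer(), breakpoint_hi = integer())
  rownames(per) <- NULL
  structure(list(per_mutation = per, n_independent = nIndep,
                 total_independent = sum(nIndep)),
            class = "OriginCallReport")
}

#' @export
print.OriginCallReport <- function(x, ...) {
  cat("OriginCallReport:", x$total_independent,
      "independent TSR origin(s) across",
      length(x$n_independent), "mutation(s)\n")
  if (nrow(x$per_mutation)) print(x$per_mutation, row.names = FALSE)
  invisible(x)
}
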