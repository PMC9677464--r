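# Seeded synthetic communities: genomes with distinct order-2 Markov
# composition, fragmented into contigs, with per-sample lognormal
# abundances, planted marker annotations from the bundled miniature
# hierarchy, masked-region features and a gold standard. Gives every other
# module a no-download test surface. Read-level effects (sequencing error,
# chimeras, strain microdiversity) are deliberately not modelled.

.AA_ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val")

#' Path to the bundled miniature marker hierarchy
#'
#' A 2-domain / 4-phylum / 6-class hierarchy with synthetic marker
#' accessions, shipped as a plain-text table in the package. It stands in
#' for a full lineage marker-set database at test scale and is labelled
#' synthetic throughout.
#' @return file path.
#' @export
mini_marker_db <- function() {
  system.file("extdata", "synthetic_marker_sets.tsv", package = "microbin",
              mustWork = TRUE)
}

#' Specification of a synthetic community
#'
#' Defaults describe the standard fixture: 10 genomes of 0.8-1.5 Mb, each
#' fragmented into 50-300 contigs, 3 samples with lognormal genome
#' abundances (median ~30x) and mild per-contig depth noise, genome
#' composition drawn per genome as an order-2 Markov chain whose transition
#' rows come from a Dirichlet (concentration 1 gives clearly separable
#' tetranucleotide signatures).
#'
#' @param n_genomes number of genomes.
#' @param n_samples number of depth samples.
#' @param contigs_per_genome integer range `c(min, max)`.
#' @param genome_length_range bp range `c(min, max)`.
#' @param abundance_meanlog,abundance_sdlog lognormal genome-by-sample
#'   abundance parameters (x-fold coverage scale).
#' @param depth_noise_sdlog per-contig lognormal depth noise.
#' @param dirichlet_concentration concentration of the per-genome Markov
#'   transition rows; lower = more distinct composition.
#' @param composition_groups optional integer vector (length `n_genomes`)
#'   assigning genomes to shared composition chains; genomes in the same
#'   group get identical transition matrices (used for
#'   differential-coverage fixtures).
#' @param taxa optional character vector assigning a hierarchy taxon to
#'   each genome; defaults to cycling the class-level taxa of the bundled
#'   hierarchy.
#' @param abundance optional explicit genome x sample abundance matrix
#'   (x-fold), overriding the lognormal draw; used e.g. for
#'   differential-coverage designs with anti-correlated profiles.
#' @param rna_fraction fraction of contigs carrying a planted rRNA or
#'   CRISPR mask feature.
#' @param trna_isotypes_per_genome unique tRNA isotypes planted per genome.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 10L, n_samples = 3L,
                           contigs_per_genome = c(50L, 300L),
                           genome_length_range = c(8e5, 1.5e6),
                           abundance_meanlog = log(30),
                           abundance_sdlog = 1,
                           depth_noise_sdlog = 0.1,
                           dirichlet_concentration = 1,
                           composition_groups = NULL,
                           taxa = NULL,
                           abundance = NULL,
                           rna_fraction = 0.05,
                           trna_isotypes_per_genome = 20L,
                           seed = 0L) {
  stopifnot(n_genomes >= 1, n_samples >= 1,
            length(contigs_per_genome) == 2L, all(contigs_per_genome >= 1),
            all(genome_length_range > 0), depth_noise_sdlog >= 0,
            abundance_sdlog >= 0, dirichlet_concentration > 0)
  if (!is.null(composition_groups))
    stopifnot(length(composition_groups) == n_genomes)
  if (!is.null(abundance))
    stopifnot(is.matrix(abundance), nrow(abundance) == n_genomes,
              ncol(abundance) == n_samples, all(abundance >= 0))
  structure(list(n_genomes = as.integer(n_genomes),
                 n_samples = as.integer(n_samples),
                 contigs_per_genome = as.integer(contigs_per_genome),
                 genome_length_range = genome_length_range,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 depth_noise_sdlog = depth_noise_sdlog,
                 dirichlet_concentration = dirichlet_concentration,
                 composition_groups = composition_groups,
                 taxa = taxa,
                 abundance = abundance,
                 rna_fraction = rna_fraction,
                 trna_isotypes_per_genome = as.integer(trna_isotypes_per_genome),
                 seed = as.integer(seed)),
            class = "community_spec")
}

# all marker accessions on the root -> taxon path
.taxon_marker_complement <- function(hierarchy, taxon) {
  acc <- character(0)
  cur <- taxon
  while (cur != "root") {
    nd <- hierarchy$nodes[[cur]]
    if (is.null(nd)) stop("unknown taxon: ", taxon)
    acc <- c(acc, unlist(nd$sets))
    cur <- nd$parent
  }
  unique(acc)
}

.rdirichlet_row <- function(alpha, k) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

#' Generate a synthetic community fixture bundle
#'
#' Deterministic under `spec$seed`. Each genome is sampled from its own
#' order-2 Markov chain, fragmented at uniform random breakpoints, given
#' per-sample depths (genome abundance x lognormal contig noise), its
#' taxon's full marker complement planted once with markers placed on
#' contigs proportional to length, plus rRNA/CRISPR mask features and tRNA
#' features. Optionally writes the five fixture files
#' (`assembly.fasta`, `annotations.gff`, `depth.tsv`, `marker_hits.tsv`,
#' `gold_standard.tsv`) to `out_dir`.
#'
#' @param spec a [community_spec()].
#' @param out_dir optional output directory.
#' @param hierarchy marker hierarchy (defaults to the bundled one).
#' @return list of class `community_bundle`: `assembly` (DNAStringSet),
#'   `depths` (matrix), `hit_table`, `gold` (data.frame contig_id,
#'   genome_id), `masks`, `rna`, `gff_lines`, `abundance` (genome x sample),
#'   `taxa`, `spec`.
#' @export
generate_community <- function(spec = community_spec(), out_dir = NULL,
                               hierarchy = load_marker_hierarchy(mini_marker_db())) {
  withr_seed(spec$seed, {
    ng <- spec$n_genomes
    classes <- sort(names(Filter(function(n) n$rank == "class",
                                 hierarchy$nodes)))
    taxa <- if (is.null(spec$taxa)) classes[((seq_len(ng) - 1L) %% length(classes)) + 1L]
            else spec$taxa
    groups <- if (is.null(spec$composition_groups)) seq_len(ng)
              else spec$composition_groups

    # per-composition-group order-2 transition matrices (16 contexts x 4)
    trans <- list()
    for (g in sort(unique(groups))) {
      m <- t(vapply(1:16, function(i)
        .rdirichlet_row(spec$dirichlet_concentration, 4L), numeric(4)))
      trans[[as.character(g)]] <- m
    }

    glens <- as.integer(round(runif(ng, spec$genome_length_range[1],
                                    spec$genome_length_range[2])))
    nconts <- as.integer(round(runif(ng, spec$contigs_per_genome[1],
                                     spec$contigs_per_genome[2])))
    abundance <- if (is.null(spec$abundance)) {
      matrix(rlnorm(ng * spec$n_samples, spec$abundance_meanlog,
                    spec$abundance_sdlog), nrow = ng)
    } else spec$abundance
    dimnames(abundance) <- list(paste0("genome_", seq_len(ng)),
                                paste0("sample_", seq_len(spec$n_samples)))

    seqs <- character(0); gold_contig <- character(0); gold_genome <- character(0)
    depth_rows <- list(); hit_rows <- list(); gff <- character(0)
    for (g in seq_len(ng)) {
      markers <- .taxon_marker_complement(hierarchy, taxa[g])
      if (glens[g] < 10L * length(markers))
        stop("genome_", g, " too short (", glens[g], " bp) for its ",
             length(markers), " markers")
      chain_seed <- (spec$seed %% 65011) * 32749L + g * 7919L
      genome <- .markov_sequence(glens[g], trans[[as.character(groups[g])]],
                                 2L, as.integer(chain_seed))
      nc <- min(nconts[g], glens[g])
      breaks <- if (nc > 1L) sort(sample.int(glens[g] - 1L, nc - 1L)) else integer(0)
      starts <- c(1L, breaks + 1L); ends <- c(breaks, glens[g])
      ids <- sprintf("g%d_c%03d", g, seq_len(nc))
      ctg <- substring(genome, starts, ends)
      lens <- ends - starts + 1L
      seqs <- c(seqs, setNames(ctg, ids))
      gold_contig <- c(gold_contig, ids)
      gold_genome <- c(gold_genome, rep(paste0("genome_", g), nc))

      # depths: genome abundance x per-contig lognormal noise
      noise <- matrix(rlnorm(nc * spec$n_samples, 0, spec$depth_noise_sdlog),
                      nrow = nc)
      depth_rows[[g]] <- sweep(noise, 2, abundance[g, ], "*")
      rownames(depth_rows[[g]]) <- ids

      # plant each marker once, contigs weighted by length
      target <- sample(seq_len(nc), length(markers), replace = TRUE,
                       prob = lens / sum(lens))
      hit_rows[[g]] <- data.frame(
        contig_id = ids[target],
        orf_id = sprintf("g%d_orf%04d", g, seq_along(markers)),
        marker_accession = markers, stringsAsFactors = FALSE)

      # mask features on a fraction of contigs; tRNAs for MIMAG tiering
      maskable <- which(lens >= 400L)
      n_mask <- round(spec$rna_fraction * nc)
      mask_idx <- if (length(maskable) && n_mask > 0)
        sample(maskable, min(n_mask, length(maskable))) else integer(0)
      rr_products <- c("16S ribosomal RNA", "23S ribosomal RNA",
                       "5S ribosomal RNA")
      for (j in seq_along(mask_idx)) {
        ci <- mask_idx[j]
        st <- sample.int(lens[ci] - 200L, 1L)
        if (j %% 2L == 1L) {
          gff <- c(gff, sprintf(
            "%s\tmicrobin_sim\trRNA\t%d\t%d\t.\t+\t.\tID=%s_rrna;product=%s",
            ids[ci], st, st + 150L, ids[ci], rr_products[(j %/% 2L) %% 3L + 1L]))
        } else {
          gff <- c(gff, sprintf(
            "%s\tmicrobin_sim\trepeat_region\t%d\t%d\t.\t+\t.\tID=%s_crispr;rpt_family=CRISPR",
            ids[ci], st, st + 180L, ids[ci]))
        }
      }
      iso <- .AA_ISOTYPES[seq_len(min(spec$trna_isotypes_per_genome,
                                      length(.AA_ISOTYPES)))]
      host <- which(lens >= 120L)
      if (length(host)) {
        tgt <- sample(host, length(iso), replace = TRUE)
        gff <- c(gff, sprintf(
          "%s\tmicrobin_sim\ttRNA\t10\t85\t.\t+\t.\tID=%s_trna%d;product=tRNA-%s",
          ids[tgt], ids[tgt], seq_along(iso), iso))
      }
    }

    assembly <- Biostrings::DNAStringSet(seqs)
    depths <- do.call(rbind, depth_rows)
    colnames(depths) <- colnames(abundance)
    hit_table <- do.call(rbind, hit_rows)
    gff <- c("##gff-version 3", sort(gff))
    gold <- data.frame(contig_id = gold_contig, genome_id = gold_genome,
                       stringsAsFactors = FALSE)

    bundle <- structure(list(
      assembly = assembly, depths = depths, hit_table = hit_table,
      gold = gold, gff_lines = gff,
      masks = NULL, rna = NULL, abundance = abundance, taxa = taxa,
      spec = spec), class = "community_bundle")

    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      Biostrings::writeXStringSet(assembly,
                                  file.path(out_dir, "assembly.fasta"),
                                  width = 80L)
      writeLines(gff, file.path(out_dir, "annotations.gff"))
      dep_lines <- c(paste0("#contig_id\t",
                            paste(colnames(depths), collapse = "\t")),
                     paste(rownames(depths),
                           apply(depths, 1, function(r)
                             paste(sprintf("%.6f", r), collapse = "\t")),
                           sep = "\t"))
      writeLines(dep_lines, file.path(out_dir, "depth.tsv"))
      write_tsv_hash(hit_table, file.path(out_dir, "marker_hits.tsv"))
      write_tsv_hash(gold, file.path(out_dir, "gold_standard.tsv"))
      bundle$out_dir <- out_dir
    }
    # parse planted annotations back through the io layer so the bundle's
    # masks/rna views are exactly what a real run would see
    tmp <- tempfile(fileext = ".gff")
    writeLines(gff, tmp)
    lens_named <- setNames(Biostrings::width(assembly), names(assembly))
    bundle$masks <- parse_gff_masks(tmp, contig_lengths = lens_named)
    bundle$rna <- parse_gff_rna_counts(tmp)
    unlink(tmp)
    bundle
  })
}

#' Composition separability diagnostic
#'
#' Contig-level ratio of between- to within-genome composition distance:
#' the mean Manhattan distance from each contig's CLR tetranucleotide
#' profile to the other genomes' profiles, divided by the mean distance to
#' the contig's own genome profile. Genomes sharing one composition chain
#' give a ratio near 1 (a contig is no closer to its own genome than to any
#' other); distinct chains push the ratio well above 1. With one contig per
#' genome the within-genome distance is 0 and `Inf` is returned as a
#' sentinel.
#'
#' @param bundle a `community_bundle`.
#' @return numeric ratio (possibly `Inf`).
#' @export
composition_separation <- function(bundle) {
  stopifnot(inherits(bundle, "community_bundle"))
  genomes <- sort(unique(bundle$gold$genome_id))
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  counts <- kmer_frequencies(bundle$assembly, ks = 4L)
  gof <- bundle$gold$genome_id[match(rownames(counts), bundle$gold$contig_id)]
  gprof <- clr(rowsum(counts, group = gof), 1)
  cprof <- clr(counts, 1)
  own <- rowSums(abs(cprof - gprof[gof, , drop = FALSE]))
  other <- vapply(seq_len(nrow(cprof)), function(i) {
    oth <- setdiff(genomes, gof[i])
    mean(rowSums(abs(sweep(gprof[oth, , drop = FALSE], 2, cprof[i, ]))))
  }, numeric(1))
  if (mean(own) == 0) return(Inf)
  mean(other) / mean(own)
}

#' Inject depth-profile contamination into a bundle
#'
#' Reassigns a seeded random fraction of contigs' depth rows to another
#' genome's abundance profile (with fresh contig noise), creating
#' mixed-signal clusters that exercise cluster splitting. The gold standard
#' is left unchanged.
#'
#' @param bundle a `community_bundle`.
#' @param fraction fraction of contigs to alter, in `[0, 1)`.
#' @param seed seed for the contig choice and fresh noise.
#' @return the modified bundle; altered ids in `$contaminated_ids`.
#' @export
inject_contamination <- function(bundle, fraction, seed = 0L) {
  stopifnot(inherits(bundle, "community_bundle"), fraction >= 0, fraction < 1)
  if (fraction == 0) {
    bundle$contaminated_ids <- character(0)
    return(bundle)
  }
  withr_seed(seed, {
    ids <- rownames(bundle$depths)
    n_alter <- round(fraction * length(ids))
    chosen <- sort(sample(ids, n_alter))
    genomes <- rownames(bundle$abundance)
    for (cid in chosen) {
      own <- bundle$gold$genome_id[bundle$gold$contig_id == cid]
      other <- sample(setdiff(genomes, own), 1L)
      noise <- rlnorm(ncol(bundle$depths), 0, bundle$spec$depth_noise_sdlog)
      bundle$depths[cid, ] <- bundle$abundance[other, ] * noise
    }
    bundle$contaminated_ids <- chosen
    bundle
  })
}
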