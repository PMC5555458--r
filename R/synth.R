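#' Configuration for the synthetic RIP-Seq experiment generator
#'
#' Bundles every knob of the simulator: a transcriptome with 3' UTR
#' isoforms, a bound-gene set whose transcripts are fold-enriched in IP
#' libraries, negative-binomial sequencing noise, miRNA families with seed
#' sites planted into UTRs, and a genetic-screen phenotype table. The
#' defaults describe the experimental design the analysis is built for:
#' three IP, two control-IP and two total-RNA libraries over a few hundred
#' genes, a bound set with four-fold IP enrichment, and an excess of
#' "interacting-family" seed sites in the UTRs of bound genes.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Length-2 integer vector `c(min, max)`: number
#'   of 3' UTR isoforms per gene is uniform on this range.
#' @param utr_length List with `mean`, `sd`, `min` (nt); lengths are normal
#'   draws truncated from below at `min` (which must be at least 8).
#' @param n_bound Number of bound genes (at most `n_genes`).
#' @param ip_effect Fold enrichment (> 1) applied to bound-gene transcripts
#'   in IP libraries.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 selects Poisson counts.
#' @param library_sizes Named numeric vector of expected total reads per
#'   sample class (`IP`, `CTRL`, `TOTAL`), or a single number for all.
#' @param design Named integer vector: replicates per class.
#' @param n_families Number of miRNA families to emit.
#' @param n_interacting How many of those families are the "interacting"
#'   subset planted preferentially into bound genes.
#' @param planted_sites_bound Mean (Poisson) number of interacting-family
#'   seed sites planted per UTR of a bound gene.
#' @param planted_sites_unbound Mean number of interacting-family sites per
#'   UTR of an unbound gene, and of non-interacting-family sites per UTR of
#'   every gene.
#' @param sites_exact If `TRUE`, the planted-site means are used as exact
#'   integer counts instead of Poisson means (useful for round-trip tests).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for
#'   per-transcript baseline abundances (normalised to proportions).
#' @param expressed_fraction Fraction of genes emitted in the
#'   expressed-gene list (the stage-expression filter stand-in).
#' @param alphabet Bases used for background UTR sequence (DNA letters).
#' @param rng_seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 500,
                       isoforms_per_gene = c(1L, 3L),
                       utr_length = list(mean = 200, sd = 60, min = 40),
                       n_bound = 50,
                       ip_effect = 4,
                       nb_dispersion = 0.05,
                       library_sizes = c(IP = 1e6, CTRL = 1e6, TOTAL = 1e6),
                       design = c(IP = 3L, CTRL = 2L, TOTAL = 2L),
                       n_families = 8,
                       n_interacting = 5,
                       planted_sites_bound = 3,
                       planted_sites_unbound = 1,
                       sites_exact = FALSE,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       expressed_fraction = 0.9,
                       alphabet = c("A", "C", "G", "T"),
                       rng_seed = 1L) {
  if (length(library_sizes) == 1L && is.null(names(library_sizes)))
    library_sizes <- c(IP = library_sizes, CTRL = library_sizes,
                       TOTAL = library_sizes)
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              utr_length = utr_length,
              n_bound = as.integer(n_bound),
              ip_effect = ip_effect,
              nb_dispersion = nb_dispersion,
              library_sizes = library_sizes,
              design = design,
              n_families = as.integer(n_families),
              n_interacting = as.integer(n_interacting),
              planted_sites_bound = planted_sites_bound,
              planted_sites_unbound = planted_sites_unbound,
              sites_exact = isTRUE(sites_exact),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              expressed_fraction = expressed_fraction,
              alphabet = alphabet,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#' @param cfg A [sim_config()] object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) stop("n_genes must be positive")
    if (n_bound < 0L || n_bound > n_genes)
      stop("n_bound must be between 0 and n_genes")
    if (length(isoforms_per_gene) != 2L || isoforms_per_gene[1L] < 1L ||
        isoforms_per_gene[2L] < isoforms_per_gene[1L])
      stop("isoforms_per_gene must be c(min, max) with 1 <= min <= max")
    if (!all(c("mean", "sd", "min") %in% names(utr_length)) ||
        utr_length$min < 8)
      stop("utr_length needs mean, sd and min >= 8")
    if (n_bound > 0L && ip_effect <= 1)
      stop("ip_effect must exceed 1 when bound genes are requested")
    if (nb_dispersion < 0) stop("nb_dispersion must be nonnegative")
    if (any(library_sizes <= 0)) stop("library sizes must be positive")
    if (n_families < 1L) stop("n_families must be positive")
    if (n_interacting < 1L || n_interacting > n_families)
      stop("n_interacting must be between 1 and n_families")
    if (planted_sites_bound < 0 || planted_sites_unbound < 0)
      stop("planted site means must be nonnegative")
    if (expressed_fraction <= 0 || expressed_fraction > 1)
      stop("expressed_fraction must be in (0, 1]")
    if (length(alphabet) < 2L)
      stop("alphabet needs at least two bases")
  })
  invisible(cfg)
}

.rna_to_dna <- function(x) chartr("U", "T", x)

# Sample miRNA families whose 6-nt site cores are mutually exclusive:
# no family's core occurs anywhere inside another family's 8mer site
# pattern, and only at its canonical offset inside its own. This makes
# planted-site ground truth exact per family.
.sim_families <- function(cfg) {
  fam_names <- sprintf("fam%02d", seq_len(cfg$n_families))
  offsets6 <- function(p8) vapply(1:3, function(o) substr(p8, o, o + 5L),
                                  character(1))
  patterns <- character(0)
  cores <- character(0)
  matures <- character(0)
  for (i in seq_len(cfg$n_families)) {
    repeat {
      mat <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                   collapse = "")
      sd7 <- derive_seed(mat)
      p7m8 <- .revcomp_rna(sd7)
      p8 <- paste0(p7m8, "A")
      core <- substr(p7m8, 2L, 7L)
      offs <- offsets6(p8)
      self_ok <- sum(offs == core) == 1L  # core only at its canonical offset
      cross_ok <- !core %in% unlist(lapply(patterns, offsets6)) &&
        !any(cores %in% offs)
      if (self_ok && cross_ok) break
    }
    patterns <- c(patterns, p8)
    cores <- c(cores, core)
    matures <- c(matures, mat)
  }
  # two members per family sharing the seed (3' halves differ)
  fam <- rep(fam_names, each = 2L)
  member <- paste0(fam, letters[rep(1:2, cfg$n_families)])
  mat2 <- vapply(matures, function(m) {
    paste0(substr(m, 1L, 12L),
           paste(sample(c("A", "C", "G", "U"), 10, replace = TRUE),
                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  data.frame(family = fam, member = member,
             mature_sequence = as.vector(rbind(matures, mat2)),
             stringsAsFactors = FALSE)
}

# Non-overlapping placement of n intervals of length w in a sequence of
# length L: always succeeds when n * w <= L.
.place_sites <- function(L, n, w = 8L) {
  if (n == 0L) return(integer(0))
  slack <- L - n * w
  x <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  x + w * (seq_len(n) - 1L)  # 0-based starts
}

#' Generate a synthetic 3' UTR annotation with planted seed sites
#'
#' Emits a UTR per isoform (DNA alphabet), a gene-to-isoform map, a miRNA
#' family table, an expressed-gene list and the ground truth of every
#' planted site. Seed sites are planted as 8mer matches (reverse complement
#' of the seed followed by A) at non-overlapping positions, replacing the
#' underlying bases; background sequence that happens to create additional
#' seed matches is re-randomised so that ground-truth site counts are
#' exact on re-scan.
#'
#' Interacting-family sites are planted with mean `planted_sites_bound`
#' per UTR in bound genes and `planted_sites_unbound` elsewhere;
#' non-interacting families are planted with mean `planted_sites_unbound`
#' everywhere.
#'
#' @param cfg A [sim_config()].
#' @return List with `utrs` (named character vector of DNA sequences),
#'   `gene_map` (data frame `gene_id`, `isoform_id`), `families`,
#'   `interacting_families` (character vector), `expressed_genes`, and
#'   `truth` (list: `bound_genes`, `planted_sites` data frame with 0-based
#'   half-open coordinates, `true_ip_effect` named per-gene vector,
#'   `isoforms` named isoform -> gene vector).
#' @export
simulate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$rng_seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  bound <- sort(sample(genes, cfg$n_bound))
  families <- .sim_families(cfg)
  seeds <- family_seeds(families)
  interacting <- names(seeds)[seq_len(cfg$n_interacting)]
  noninteracting <- setdiff(names(seeds), interacting)
  pat_dna <- .rna_to_dna(vapply(seeds, function(s)
    paste0(.revcomp_rna(s), "A"), character(1)))

  utrs <- character(0)
  gene_map <- list()
  planted <- list()
  for (g in genes) {
    n_iso <- sample(cfg$isoforms_per_gene[1L]:cfg$isoforms_per_gene[2L], 1L)
    is_bound <- g %in% bound
    for (j in seq_len(n_iso)) {
      iso <- sprintf("%s.%d", g, j)
      res <- .sim_one_utr(cfg, g, is_bound, interacting, noninteracting,
                          pat_dna, seeds)
      utrs[[iso]] <- res$seq
      if (nrow(res$sites) > 0L) {
        res$sites$isoform_id <- iso
        planted[[iso]] <- res$sites
      }
      gene_map[[iso]] <- data.frame(gene_id = g, isoform_id = iso,
                                    stringsAsFactors = FALSE)
    }
  }
  gene_map <- do.call(rbind, gene_map)
  rownames(gene_map) <- NULL
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(family = character(0), start = integer(0), end = integer(0),
               site_type = character(0), isoform_id = character(0),
               stringsAsFactors = FALSE)
  planted <- planted[, c("isoform_id", "family", "start", "end",
                         "site_type")]
  rownames(planted) <- NULL
  effect <- stats::setNames(ifelse(genes %in% bound, cfg$ip_effect, 1),
                            genes)
  expressed <- sort(sample(genes,
                           max(1L, round(cfg$expressed_fraction *
                                           cfg$n_genes))))
  list(utrs = utrs, gene_map = gene_map, families = families,
       interacting_families = interacting, expressed_genes = expressed,
       truth = list(bound_genes = bound, planted_sites = planted,
                    true_ip_effect = effect,
                    isoforms = stats::setNames(gene_map$gene_id,
                                               gene_map$isoform_id)))
}

# One UTR: draw background, plant sites, scrub accidental matches.
.sim_one_utr <- function(cfg, gene, is_bound, interacting, noninteracting,
                         pat_dna, seeds) {
  mean_int <- if (is_bound) cfg$planted_sites_bound else
    cfg$planted_sites_unbound
  for (attempt in seq_len(50L)) {
    L <- max(cfg$utr_length$min,
             round(stats::rnorm(1L, cfg$utr_length$mean, cfg$utr_length$sd)))
    if (cfg$sites_exact) {
      n_int <- as.integer(mean_int)
      n_non <- if (length(noninteracting)) {
        as.integer(cfg$planted_sites_unbound)
      } else 0L
    } else {
      n_int <- stats::rpois(1L, mean_int)
      n_non <- if (length(noninteracting)) {
        stats::rpois(1L, cfg$planted_sites_unbound)
      } else 0L
    }
    fam_draw <- c(
      if (n_int > 0L) sample(interacting, n_int, replace = TRUE),
      if (n_non > 0L) sample(noninteracting, n_non, replace = TRUE))
    n_tot <- length(fam_draw)
    if (8L * n_tot > L) {
      # exact requests are non-negotiable; Poisson draws are retried
      # (counts conditional on fitting; upper-tail truncation only)
      if (cfg$sites_exact)
        stop("cannot fit ", n_tot, " planted sites in a ", L,
             "-nt UTR of gene ", gene)
      next
    }
    chars <- sample(cfg$alphabet, L, replace = TRUE)
    sites <- data.frame(family = character(0), start = integer(0),
                        end = integer(0), site_type = character(0),
                        stringsAsFactors = FALSE)
    planted_pos <- integer(0)
    if (n_tot > 0L) {
      starts0 <- .place_sites(L, n_tot)
      fam_draw <- sample(fam_draw)
      for (k in seq_len(n_tot)) {
        s1 <- starts0[k] + 1L  # 1-based
        chars[s1:(s1 + 7L)] <- strsplit(pat_dna[[fam_draw[k]]], "")[[1L]]
      }
      planted_pos <- unlist(lapply(starts0, function(s) (s + 1L):(s + 8L)))
      sites <- data.frame(family = fam_draw, start = as.integer(starts0),
                          end = as.integer(starts0 + 8L),
                          site_type = "8mer", stringsAsFactors = FALSE)
    }
    seq <- .scrub_utr(chars, planted_pos, sites, seeds, cfg$alphabet)
    if (!is.null(seq)) {
      o <- order(sites$start)
      return(list(seq = seq, sites = sites[o, , drop = FALSE]))
    }
  }
  stop("could not generate a clean UTR for gene ", gene,
       " (planted sites keep colliding with background matches)")
}

# Rescan and re-randomise bases that create unplanned seed matches.
# Returns the sequence string, or NULL when a match cannot be removed
# without touching a planted site (caller redraws the whole UTR).
.scrub_utr <- function(chars, planted_pos, sites, seeds, alphabet) {
  key <- paste(sites$family, sites$start, sites$end)
  for (iter in seq_len(100L)) {
    seq <- paste(chars, collapse = "")
    extra <- NULL
    for (f in names(seeds)) {
      det <- find_seed_sites(seq, seeds[[f]])
      if (nrow(det) == 0L) next
      dk <- paste(f, det$start, det$end)
      miss <- !(dk %in% key)
      if (any(miss)) {
        extra <- det[miss, , drop = FALSE][1L, , drop = FALSE]
        break
      }
    }
    if (is.null(extra)) return(seq)
    win <- (extra$start + 1L):extra$end  # 1-based positions of the match
    free <- setdiff(win, planted_pos)
    if (length(free) == 0L) return(NULL)
    pos <- if (length(free) == 1L) free else sample(free, 1L)
    alt <- setdiff(alphabet, chars[pos])
    if (length(alt) == 0L) return(NULL)
    chars[pos] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  }
  NULL
}

#' Generate a synthetic RIP-Seq count matrix
#'
#' Per-transcript baseline abundances are log-normal, normalised to
#' proportions; the expected count of transcript i in sample s is
#' `baseline_i * library_size_s * e`, where `e` is the configured
#' `ip_effect` for transcripts of bound genes in IP libraries and 1
#' otherwise. Counts are negative binomial with
#' `variance = mu + alpha * mu^2` (Poisson when `nb_dispersion = 0`).
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_annotation()] (supplies the
#'   transcript list and per-gene fold enrichment).
#' @return Integer count matrix (transcripts x samples) with columns named
#'   `"CLASS:replicate"`.
#' @export
simulate_counts <- function(cfg, truth) {
  validate_sim_config(cfg)
  if (is.null(truth$isoforms) || length(truth$isoforms) == 0L)
    stop("truth must carry an isoform -> gene mapping")
  set.seed((cfg$rng_seed + 1L) %% .Machine$integer.max)
  iso <- names(truth$isoforms)
  gene_of <- truth$isoforms
  n_tx <- length(iso)
  baseline <- stats::rlnorm(n_tx, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline <- baseline / sum(baseline)

  if (!all(names(cfg$design) %in% names(cfg$library_sizes)))
    stop("library_sizes must name every sample class in the design")
  cls <- rep(names(cfg$design), times = cfg$design)
  repn <- unlist(lapply(cfg$design, seq_len), use.names = FALSE)
  cols <- paste0(cls, ":", repn)
  libs <- cfg$library_sizes[cls]
  eff_tx <- truth$true_ip_effect[gene_of]

  m <- matrix(0L, n_tx, length(cols), dimnames = list(iso, cols))
  for (j in seq_along(cols)) {
    mu <- baseline * libs[j] * (if (cls[j] == "IP") eff_tx else 1)
    m[, j] <- if (cfg$nb_dispersion == 0) {
      stats::rpois(n_tx, mu)
    } else {
      stats::rnbinom(n_tx, mu = mu, size = 1 / cfg$nb_dispersion)
    }
  }
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic phenotype (arrest-penetrance) table
#'
#' For each genotype, the number of arrested animals is binomial with the
#' given per-animal arrest probability, emulating scored L1-arrest
#' penetrance in a genetic screen.
#'
#' @param genotypes Data frame with columns `label`, `n`, `arrest_prob`.
#' @param rng_seed Integer seed.
#' @return Data frame with `genotype`, `n_scored`, `n_arrested`.
#' @export
simulate_phenotypes <- function(genotypes, rng_seed = 1L) {
  need <- c("label", "n", "arrest_prob")
  if (!all(need %in% names(genotypes)))
    stop("genotypes needs columns: ", paste(need, collapse = ", "))
  if (any(genotypes$n <= 0)) stop("n must be positive")
  if (any(genotypes$arrest_prob < 0 | genotypes$arrest_prob > 1))
    stop("arrest_prob must be in [0, 1]")
  set.seed(rng_seed)
  data.frame(genotype = genotypes$label,
             n_scored = as.integer(genotypes$n),
             n_arrested = stats::rbinom(nrow(genotypes), genotypes$n,
                                        genotypes$arrest_prob),
             stringsAsFactors = FALSE)
}
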