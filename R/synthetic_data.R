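#' Simulation configuration for a two-clade symbiont panel
#'
#' Defaults emulate the study system: 12 in-group taxa (5 clade I, 7 clade II)
#' plus one outgroup; ten genes from ~230 bp to ~3.4 kb; clade I with a 1.5x
#' substitution-rate multiplier and a lower GC equilibrium (0.32 vs 0.38);
#' HKY with kappa = 4; uvrB/uvrC/mutY pseudogenized on the clade-I stem, uvrD
#' on the Ifos_S and Apha_S tip branches and mutY on the Rma tip branch, each
#' switching to neutral evolution (omega = 1) with an accumulating deletion
#' process.
#'
#' @param tree Newick string (or \code{ape::phylo}) with branch lengths;
#'   internal-node labels name branches for pseudogenization.
#' @param clades Named character vector tip -> clade (\code{I}, \code{II},
#'   \code{outgroup}).
#' @param rate_multiplier Named per-clade rate scalars.
#' @param gc_equilibrium Named per-clade GC equilibria (0-1).
#' @param gc_ancestral GC equilibrium of the root/outgroup lineage.
#' @param kappa Transition/transversion rate ratio.
#' @param gene_specs data.frame with columns gene_id, codons, omega.
#' @param pseudogenization data.frame with columns gene_id, branch (label of
#'   the branch's child node/tip), deletion_rate (deletions per site per unit
#'   branch length), mean_len (mean geometric deletion length, bases).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @export
simulation_config <- function(
    tree = paste0(
      "(Bsep_S:0.9,((Akaw_S:0.1,Clau_S:0.1,(Pkil_S:0.04,Psoy_S:0.04)",
      "soykil:0.06,Vok:0.1)cladeI:0.3,(Cpac_S:0.1,Cfau_S:0.1,Cnau_S:0.1,",
      "Pste_S:0.1,Rma:0.1,Ifos_S:0.1,Apha_S:0.1)cladeII:0.3)ingroup:0.5);"),
    clades = c(Bsep_S = "outgroup",
               Akaw_S = "I", Clau_S = "I", Pkil_S = "I", Psoy_S = "I", Vok = "I",
               Cpac_S = "II", Cfau_S = "II", Cnau_S = "II", Pste_S = "II",
               Rma = "II", Ifos_S = "II", Apha_S = "II"),
    rate_multiplier = c(I = 1.5, II = 1.0),
    gc_equilibrium = c(I = 0.32, II = 0.38),
    gc_ancestral = 0.38,
    kappa = 4,
    gene_specs = data.frame(
      gene_id = c("uvrA", "uvrB", "uvrC", "uvrD", "uvrDp",
                  "mfd", "groEL", "groES", "galU", "mutY"),
      codons  = c(939L, 665L, 595L, 720L, 1053L, 1142L, 549L, 77L, 300L, 350L),
      omega   = c(0.16, 0.20, 0.20, 0.26, 0.44, 0.25, 0.18, 0.35, 0.20, 0.20),
      stringsAsFactors = FALSE),
    pseudogenization = data.frame(
      gene_id = c("uvrB", "uvrC", "mutY", "uvrD", "uvrD", "mutY"),
      branch  = c("cladeI", "cladeI", "cladeI", "Ifos_S", "Apha_S", "Rma"),
      deletion_rate = 0.035,
      mean_len = 20,
      stringsAsFactors = FALSE),
    seed = 1L) {
  cfg <- list(tree = tree, clades = clades, rate_multiplier = rate_multiplier,
              gc_equilibrium = gc_equilibrium, gc_ancestral = gc_ancestral,
              kappa = kappa, gene_specs = gene_specs,
              pseudogenization = pseudogenization, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree else ape::read.tree(text = cfg$tree)
  if (is.null(tree)) stop("cannot parse the tree")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  missing_clade <- setdiff(tree$tip.label, names(cfg$clades))
  if (length(missing_clade)) {
    stop("tips without clade assignment: ", paste(missing_clade, collapse = ", "))
  }
  gcs <- c(cfg$gc_equilibrium, cfg$gc_ancestral)
  if (any(gcs <= 0 | gcs >= 1)) stop("GC equilibria must be in (0,1)")
  if (anyDuplicated(cfg$gene_specs$gene_id)) stop("duplicate gene_id in gene_specs")
  if (any(cfg$gene_specs$codons < 1L)) stop("gene lengths must be >= 1 codon")
  if (any(cfg$gene_specs$omega < 0 | cfg$gene_specs$omega > 1)) {
    stop("omega must be in [0,1]")
  }
  ps <- cfg$pseudogenization
  if (nrow(ps)) {
    bad_gene <- setdiff(ps$gene_id, cfg$gene_specs$gene_id)
    if (length(bad_gene)) stop("pseudogenization of unknown gene(s): ",
                               paste(bad_gene, collapse = ", "))
    labels <- c(tree$tip.label, tree$node.label)
    bad_branch <- setdiff(ps$branch, labels)
    if (length(bad_branch)) stop("pseudogenization on unknown branch(es): ",
                                 paste(bad_branch, collapse = ", "))
    if (any(ps$deletion_rate < 0)) stop("deletion_rate must be >= 0")
    if (any(ps$mean_len < 1)) stop("mean deletion length must be >= 1")
  }
  invisible(TRUE)
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Simulate an in-frame root coding sequence
#'
#' Codons drawn iid from position-independent base frequencies with the given
#' GC equilibrium (A = T = (1 - piGC)/2, G = C = piGC/2), rejecting stop
#' codons; the sequence starts with ATG and ends with a stop codon drawn
#' proportionally to its base probabilities.
#'
#' @param length_codons Total codons including start and stop; values below 2
#'   produce the minimal ATG + stop sequence with a warning.
#' @param gc_equilibrium Equilibrium GC fraction in (0,1).
#' @param seed Optional seed.
#' @return DNA string of \code{3 * max(length_codons, 2)} bases.
#' @export
simulate_root_sequence <- function(length_codons, gc_equilibrium, seed = NULL) {
  if (length_codons < 1L) stop("length must be >= 1 codon")
  if (!is.null(seed)) set.seed(seed)
  freqs <- .gc_freqs(gc_equilibrium)
  grid <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  codons <- paste0(.BASES[grid$b1], .BASES[grid$b2], .BASES[grid$b3])
  probs <- freqs[grid$b1] * freqs[grid$b2] * freqs[grid$b3]
  sense <- !(codons %in% .STOPS)
  if (length_codons < 2L) {
    warning("minimal sequence: emitting ATG + stop only")
    length_codons <- 2L
  }
  body <- if (length_codons > 2L) {
    sample(codons[sense], length_codons - 2L, replace = TRUE,
           prob = probs[sense] / sum(probs[sense]))
  } else character(0)
  stop_probs <- probs[match(.STOPS, codons)]
  stop_codon <- sample(.STOPS, 1L, prob = stop_probs / sum(stop_probs))
  paste(c("ATG", body, stop_codon), collapse = "")
}

#' Evolve a sequence along one branch under HKY with selection thinning
#'
#' The HKY rate matrix (equilibrium set by \code{gc_equilibrium}, A = T,
#' G = C) is scaled so that \code{branch_length} equals the expected neutral
#' substitutions per site. Neutral evolution (\code{omega = 1}) uses the exact
#' finite-time transition matrix per site. Under selection
#' (\code{omega < 1}), substitution events are sampled by uniformization and
#' non-synonymous proposals are accepted with probability \code{omega};
#' proposals creating an internal stop codon are rejected (purifying
#' selection against nonsense), so the sequence must be in frame.
#'
#' @param seq DNA string over \code{A,C,G,T}.
#' @param branch_length Expected neutral substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param gc_equilibrium Equilibrium GC fraction.
#' @param omega Non-synonymous acceptance probability in [0,1].
#' @param seed Optional seed.
#' @return Evolved DNA string with attribute \code{"substitutions"} (accepted
#'   events under selection; observed site differences on the neutral path).
#' @export
evolve_sequence <- function(seq, branch_length, kappa = 4, gc_equilibrium = 0.38,
                            omega = 1, seed = NULL) {
  if (branch_length < 0) stop("branch length must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- .seq_ints(seq)
  L <- length(x)
  if (branch_length == 0 || L == 0L) {
    out <- seq; attr(out, "substitutions") <- 0L
    return(out)
  }
  freqs <- .gc_freqs(gc_equilibrium)
  if (omega >= 1) {
    eig <- .hky_eigen(freqs, kappa)
    P <- .hky_pmat(eig, branch_length)
    new <- x
    for (b in 1:4) {
      idx <- which(x == b)
      if (length(idx)) new[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                              prob = P[b, ])
    }
    out <- paste(.BASES[new], collapse = "")
    attr(out, "substitutions") <- sum(new != x)
    return(out)
  }
  if (L %% 3L != 0L) stop("selection (omega < 1) requires an in-frame sequence")
  Q <- .hky_Q(freqs, kappa)
  lambda <- max(-diag(Q))
  J <- Q / lambda
  diag(J) <- 1 + diag(Q) / lambda
  cumJ <- t(apply(J, 1, cumsum))
  aa64 <- .aa_by_code()
  ncod <- L %/% 3L
  n_events <- rpois(1L, lambda * branch_length * L)
  nsub <- 0L
  if (n_events > 0L) {
    sites <- sample.int(L, n_events, replace = TRUE)
    u_jump <- runif(n_events)
    u_acc <- runif(n_events)
    for (e in seq_len(n_events)) {
      site <- sites[e]
      cur <- x[site]
      j <- 1L + sum(u_jump[e] > cumJ[cur, ])
      if (j == cur || j > 4L) next
      ci <- (site - 1L) %/% 3L
      base_i <- ci * 3L
      b1 <- x[base_i + 1L]; b2 <- x[base_i + 2L]; b3 <- x[base_i + 3L]
      old_code <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
      pos <- site - base_i
      nb <- c(b1, b2, b3); nb[pos] <- j
      new_code <- (nb[1] - 1L) * 16L + (nb[2] - 1L) * 4L + nb[3]
      aa_old <- aa64[old_code]; aa_new <- aa64[new_code]
      if (aa_new == "*" && ci < ncod - 1L) next        # internal nonsense rejected
      if (aa_new != aa_old && u_acc[e] > omega) next   # non-synonymous thinning
      x[site] <- j
      nsub <- nsub + 1L
    }
  }
  out <- paste(.BASES[x], collapse = "")
  attr(out, "substitutions") <- nsub
  out
}

#' Apply a pseudogenization deletion process
#'
#' Deletion events follow a Poisson process along the sequence (expected
#' \code{deletion_rate * length} events) with geometric lengths of mean
#' \code{mean_len} (support >= 1). Events are applied sequentially on the
#' current sequence; deletions running past the 3' end are truncated and
#' logged.
#'
#' @param seq DNA string.
#' @param deletion_rate Expected deletion events per site.
#' @param mean_len Mean deletion length in bases.
#' @param seed Optional seed.
#' @return List with \code{sequence}, \code{events} (data.frame start,
#'   length, requested, truncated; start in the coordinates of the sequence
#'   at event time), and \code{kept} (indices of the input retained).
#' @export
apply_pseudogenization <- function(seq, deletion_rate, mean_len = 20, seed = NULL) {
  if (deletion_rate < 0) stop("deletion_rate must be >= 0")
  if (mean_len < 1) stop("mean_len must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L0 <- nchar(seq)
  kept <- seq_len(L0)
  n <- rpois(1L, deletion_rate * L0)
  events <- data.frame(start = integer(0), length = integer(0),
                       requested = integer(0), truncated = logical(0))
  if (n > 0L) {
    for (e in seq_len(n)) {
      L <- length(kept)
      if (L == 0L) break
      start <- sample.int(L, 1L)
      len <- rgeom(1L, 1 / mean_len) + 1L
      realized <- min(len, L - start + 1L)
      events <- rbind(events, data.frame(start = start, length = realized,
                                         requested = len,
                                         truncated = realized < len))
      kept <- kept[-(start:(start + realized - 1L))]
    }
  }
  ch <- .chars(seq)
  list(sequence = paste(ch[kept], collapse = ""), events = events, kept = kept)
}

# per-edge clade assignment: "I"/"II" when every descendant tip is in that
# clade, otherwise "ancestral" (root-side and outgroup edges)
.edge_clades <- function(tree, clades) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  # postorder accumulation of descendant tips
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- desc[[tree$edge[e, 2]]]
    cl <- unique(clades[tips])
    if (length(cl) == 1L && cl %in% c("I", "II")) cl else "ancestral"
  }, character(1))
}

.node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else if (!is.null(tree$node.label)) tree$node.label[node - ntip]
  else ""
}

#' Simulate a full gene-by-symbiont dataset with ground truth
#'
#' Each gene's root sequence evolves down the tree; branches whose descendant
#' tips all belong to one clade use that clade's rate multiplier and GC
#' equilibrium, remaining branches the ancestral values. When a gene reaches
#' its configured pseudogenization branch it switches to neutral evolution
#' (omega = 1) and a deletion process runs on that branch and every
#' descendant branch (per-branch expected deletions =
#' \code{deletion_rate * branch_length_effective * length}). True alignments
#' are emitted by tracking homology through the deletions, so no realignment
#' is needed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{matrix} (a \code{gene_matrix}), \code{alignments}
#'   (per gene, named gapped sequences incl. the outgroup), \code{metadata}
#'   (data.frame), and \code{truth} (config echo, per-edge substitution
#'   counts, per-tip GC, deletion event log).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  .validate_sim_config(config)
  set.seed(config$seed)
  tree <- if (inherits(config$tree, "phylo")) config$tree else ape::read.tree(text = config$tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edge_clade <- .edge_clades(tree, config$clades)
  edge_mult <- ifelse(edge_clade == "ancestral", 1,
                      config$rate_multiplier[edge_clade])
  edge_gc <- ifelse(edge_clade == "ancestral", config$gc_ancestral,
                    config$gc_equilibrium[edge_clade])
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  genes <- config$gene_specs
  ps <- config$pseudogenization
  tip_seq <- list(); tip_kept <- list(); tip_status <- list()
  edge_subs <- matrix(0L, nrow(genes), nrow(tree$edge),
                      dimnames = list(genes$gene_id, NULL))
  del_log <- list()

  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene_id[gi]
    root_seq <- simulate_root_sequence(genes$codons[gi], config$gc_ancestral)
    ps_g <- ps[ps$gene_id == g, , drop = FALSE]
    tip_seq[[g]] <- list(); tip_kept[[g]] <- list(); tip_status[[g]] <- list()

    walk <- function(node, seq, kept, pseudo) {
      for (e in children[[as.character(node)]]) {
        child <- tree$edge[e, 2]
        lab <- .node_label(tree, child)
        bl_eff <- tree$edge.length[e] * edge_mult[e]
        pseudo2 <- pseudo || (nzchar(lab) && lab %in% ps_g$branch)
        seq2 <- seq; kept2 <- kept
        if (pseudo2 && nrow(ps_g)) {
          dl <- apply_pseudogenization(seq2, ps_g$deletion_rate[1] * bl_eff,
                                       ps_g$mean_len[1])
          if (nrow(dl$events)) {
            del_log[[length(del_log) + 1L]] <<- cbind(
              data.frame(gene_id = g, branch = if (nzchar(lab)) lab else child),
              dl$events)
          }
          seq2 <- dl$sequence
          kept2 <- kept2[dl$kept]
        }
        omega_e <- if (pseudo2) 1 else genes$omega[gi]
        seq2 <- evolve_sequence(seq2, bl_eff, kappa = config$kappa,
                                gc_equilibrium = edge_gc[e], omega = omega_e)
        edge_subs[gi, e] <<- attr(seq2, "substitutions")
        seq2 <- as.character(seq2)
        if (child <= ntip) {
          tip <- tree$tip.label[child]
          tip_seq[[g]][[tip]] <<- seq2
          tip_kept[[g]][[tip]] <<- kept2
          tip_status[[g]][[tip]] <<- if (pseudo2) "degraded" else "intact"
        } else {
          walk(child, seq2, kept2, pseudo2)
        }
      }
    }
    walk(root, root_seq, seq_len(nchar(root_seq)), FALSE)
  }

  tips <- tree$tip.label
  records <- do.call(rbind, lapply(genes$gene_id, function(g) {
    data.frame(symbiont_id = tips, gene_id = g,
               clade = unname(config$clades[tips]),
               status = vapply(tips, function(tp) tip_status[[g]][[tp]], ""),
               sequence = vapply(tips, function(tp) tip_seq[[g]][[tp]], ""),
               stringsAsFactors = FALSE)
  }))
  records$orf_ok <- records$status != "intact" |
    vapply(records$sequence, .orf_ok, NA)
  outg <- names(config$clades)[config$clades == "outgroup"][1]
  gm <- structure(list(records = records, gene_order = genes$gene_id,
                       symbiont_order = tips, outgroup_id = outg),
                  class = "gene_matrix")

  alignments <- setNames(lapply(genes$gene_id, function(g) {
    L <- 3L * max(genes$codons[genes$gene_id == g], 2L)
    setNames(vapply(tips, function(tp) {
      row <- rep("-", L)
      row[tip_kept[[g]][[tp]]] <- .chars(tip_seq[[g]][[tp]])
      paste(row, collapse = "")
    }, ""), tips)
  }), genes$gene_id)

  tip_gc <- matrix(NA_real_, nrow(genes), ntip,
                   dimnames = list(genes$gene_id, tips))
  for (g in genes$gene_id) for (tp in tips) {
    tip_gc[g, tp] <- gc_content(tip_seq[[g]][[tp]])$gc_fraction
  }

  truth <- list(
    config = config,
    edge_changes = edge_subs,
    edge_table = data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                            child_label = vapply(tree$edge[, 2],
                                                 function(n) .node_label(tree, n), ""),
                            length = tree$edge.length, clade = edge_clade),
    tip_gc = tip_gc,
    deletions = if (length(del_log)) do.call(rbind, del_log) else
      data.frame(gene_id = character(0), branch = character(0),
                 start = integer(0), length = integer(0),
                 requested = integer(0), truncated = logical(0))
  )

  metadata <- records[, c("symbiont_id", "gene_id", "clade", "status")]
  list(matrix = gm, alignments = alignments, metadata = metadata, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes \code{genes.fa} (headers \code{symbiont|gene}), one alignment FASTA
#' per gene under \code{aln/}, \code{meta.tsv}, and \code{truth.json}.
#'
#' @param sim Result of \code{\link{simulate_dataset}}.
#' @param dir Output directory (created if needed).
#' @param delim Header delimiter.
#' @export
write_dataset <- function(sim, dir, delim = "|") {
  dir.create(file.path(dir, "aln"), recursive = TRUE, showWarnings = FALSE)
  r <- sim$matrix$records
  write_fasta(paste(r$symbiont_id, r$gene_id, sep = delim), r$sequence,
              file.path(dir, "genes.fa"))
  for (g in names(sim$alignments)) {
    aln <- sim$alignments[[g]]
    write_fasta(names(aln), unname(aln), file.path(dir, "aln", paste0(g, ".fa")))
  }
  write.table(sim$metadata, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config$tree <- if (inherits(truth$config$tree, "phylo")) {
    ape::write.tree(truth$config$tree)
  } else truth$config$tree
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a directory of per-gene alignment FASTA files
#'
#' @param dir Directory containing \code{<gene>.fa} files whose record
#'   headers are symbiont ids.
#' @return Named list (by gene) of named character vectors.
#' @export
read_alignment_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no alignment FASTA files in ", dir)
  out <- lapply(files, function(f) {
    df <- read_fasta(f)
    setNames(df$sequence, vapply(strsplit(df$header, "[ \t]"), `[`, "", 1L))
  })
  setNames(out, sub("\\.(fa|fasta)$", "", basename(files)))
}
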