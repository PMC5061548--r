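# Independent oracles used by the test suite. These deliberately do NOT
# share code with the package internals they check.

# ---- brute-force local alignment -------------------------------------
# Enumerates every local alignment that starts and ends on a match column
# (the optimum is always attained by one, or by the empty alignment) with
# branch-and-bound pruning. Gap runs cost open + (len-1) * extend; a gap
# run switching sides re-opens.
sw_enumerate <- function(a, b, match = 1, mismatch = 2, gap_open = 5,
                         gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  recurse <- function(i, j, sc, last) {
    if (last == "m" && sc > best) best <<- sc
    if (i < n && j < m) {
      s2 <- sc + if (av[i + 1] == bv[j + 1]) match else -mismatch
      if (s2 + min(n - i - 1, m - j - 1) * match > best || s2 > best) {
        recurse(i + 1, j + 1, s2, "m")
      }
    }
    if (i < n) {
      cost <- if (last == "x") gap_extend else gap_open
      s2 <- sc - cost
      if (s2 + min(n - i - 1, m - j) * match > best) recurse(i + 1, j, s2, "x")
    }
    if (j < m) {
      cost <- if (last == "y") gap_extend else gap_open
      s2 <- sc - cost
      if (s2 + min(n - i, m - j - 1) * match > best) recurse(i, j + 1, s2, "y")
    }
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (av[i] == bv[j]) recurse(i, j, match, "m")
    }
  }
  best
}

# ---- brute-force duplication-loss reconciliation ---------------------
# Minimum duplications + losses over ALL valid gene-node -> species-node
# mappings (each internal node maps to an ancestor-or-equal of its
# children's mappings).
recon_brute_force <- function(gphy, sphy, leaf_species) {
  n_tip <- length(gphy$tip.label)
  n_all <- n_tip + gphy$Nnode
  gkids <- vector("list", n_all)
  for (e in seq_len(nrow(gphy$edge))) {
    gkids[[gphy$edge[e, 1]]] <- c(gkids[[gphy$edge[e, 1]]], gphy$edge[e, 2])
  }
  s_all <- length(sphy$tip.label) + sphy$Nnode
  spar <- rep(NA_integer_, s_all)
  spar[sphy$edge[, 2]] <- sphy$edge[, 1]
  sanc <- lapply(seq_len(s_all), function(v) {
    out <- v
    while (!is.na(spar[v])) { v <- spar[v]; out <- c(out, v) }
    out
  })
  sdepth <- lengths(sanc)
  slca <- function(u, v) {
    common <- intersect(sanc[[u]], sanc[[v]])
    common[which.max(sdepth[common])]
  }
  sdist <- function(up, down) {
    # edges from ancestor `up` down to `down`
    (sdepth[down] - sdepth[up])
  }

  leafM <- match(leaf_species, sphy$tip.label)
  internal <- rev(setdiff(unique(gphy$edge[, 1]), gphy$edge[, 2]))
  # postorder list of internal nodes
  post <- integer(0)
  visit <- function(v) {
    if (v > n_tip) {
      for (ch in gkids[[v]]) visit(ch)
      post <<- c(post, v)
    }
  }
  root <- setdiff(unique(gphy$edge[, 1]), gphy$edge[, 2])
  visit(root)

  M <- integer(n_all)
  M[seq_len(n_tip)] <- leafM
  best <- Inf

  cost_of <- function() {
    dup <- 0; loss <- 0
    for (v in post) {
      ch <- gkids[[v]]
      lca <- slca(M[ch[1]], M[ch[2]])
      is_dup <- !(M[v] == lca && M[ch[1]] != M[v] && M[ch[2]] != M[v])
      dup <- dup + is_dup
      for (c0 in ch) {
        loss <- loss + sdist(M[v], M[c0]) - (!is_dup)
      }
    }
    dup + loss
  }

  assign_node <- function(k) {
    if (k > length(post)) {
      best <<- min(best, cost_of())
      return(invisible(NULL))
    }
    v <- post[k]
    ch <- gkids[[v]]
    lca <- slca(M[ch[1]], M[ch[2]])
    for (cand in sanc[[lca]]) {
      M[v] <<- cand
      assign_node(k + 1)
    }
    invisible(NULL)
  }
  assign_node(1)
  best
}

# random rooted binary gene tree over k species, with "sp|i" tip labels
random_gene_tree_case <- function(n_leaves, n_species, seed) {
  set.seed(seed)
  gphy <- ape::rtree(n_leaves, rooted = TRUE)
  sphy <- if (n_species == 2) {
    ape::read.tree(text = sprintf("(%s:1,%s:1);", "s1", "s2"))
  } else {
    ape::rtree(n_species, rooted = TRUE, tip.label = paste0("s", seq_len(n_species)))
  }
  sp <- sample(sphy$tip.label, n_leaves, replace = TRUE)
  gphy$tip.label <- sprintf("%s|%d", sp, seq_len(n_leaves))
  list(gene = gphy, species = sphy, leaf_species = sp)
}

# small fast config for simulation-heavy tests (overridable defaults)
quick_config <- function(...) {
  args <- utils::modifyList(
    list(root_seq_len = 399, read_len = 80, coverage = 5, flank_len = 200),
    list(...), keep.null = TRUE)
  do.call(sim_config, args)
}
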