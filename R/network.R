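#' Network architecture configuration
#'
#' Defaults follow the published architecture: four graph-convolution
#' layers per stream, batch normalisation after each activation,
#' dropout 0.1 on the convolution layers, per-residue max pooling of the
#' atom stream, concatenation with the residue stream, a two-hidden-layer
#' MLP producing one score per residue, and a sigmoid squashing so
#' per-residue outputs live in [0,1]; the global score is their mean.
#'
#' @param n_layers_atom,n_layers_residue convolution depth per stream.
#' @param hidden_dim_atom,hidden_dim_residue hidden widths.
#' @param mlp_hidden_dims integer vector of MLP hidden widths.
#' @param dropout dropout rate on convolution layers (training only).
#' @param output_activation \code{"sigmoid"}, \code{"clamp"} or
#'   \code{"none"}.
#' @param use_atom_stream,use_residue_stream ablation switches dropping
#'   one stream from the concatenation.
#' @param bn_momentum,bn_eps batch-normalisation running-statistics
#'   momentum and variance floor.
#' @return list of class \code{qa_model_config}.
#' @export
model_config <- function(n_layers_atom = 4L, n_layers_residue = 4L,
                         hidden_dim_atom = 128L, hidden_dim_residue = 128L,
                         mlp_hidden_dims = c(128L, 64L), dropout = 0.1,
                         output_activation = c("sigmoid", "clamp", "none"),
                         use_atom_stream = TRUE, use_residue_stream = TRUE,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  output_activation <- match.arg(output_activation)
  stopifnot(n_layers_atom >= 1, n_layers_residue >= 1,
            dropout >= 0, dropout < 1,
            use_atom_stream || use_residue_stream)
  structure(list(n_layers_atom = as.integer(n_layers_atom),
                 n_layers_residue = as.integer(n_layers_residue),
                 hidden_dim_atom = as.integer(hidden_dim_atom),
                 hidden_dim_residue = as.integer(hidden_dim_residue),
                 mlp_hidden_dims = as.integer(mlp_hidden_dims),
                 dropout = dropout, output_activation = output_activation,
                 use_atom_stream = use_atom_stream,
                 use_residue_stream = use_residue_stream,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "qa_model_config")
}

# uniform fan-in initialisation (PyTorch Linear convention)
.qa_init_mat <- function(d_in, d_out) {
  bound <- 1 / sqrt(d_in)
  matrix(runif(d_in * d_out, -bound, bound), d_in, d_out)
}

.qa_init_conv_layer <- function(d_in, d_out, n_agg) {
  l <- list(W_c = .qa_init_mat(d_in, d_out),
            b = runif(d_out, -1 / sqrt(d_in), 1 / sqrt(d_in)),
            bn_gamma = rep(1, d_out), bn_beta = rep(0, d_out),
            bn_mean = rep(0, d_out), bn_var = rep(1, d_out))
  aggs <- c("W_s", "W_o")[seq_len(n_agg)]
  for (a in aggs) l[[a]] <- .qa_init_mat(d_in, d_out)
  l
}

#' Initialise network parameters
#'
#' @param mcfg a [model_config()].
#' @param d_atom_in atom feature width (11 for the one-hot types).
#' @param d_res_in residue feature width (provider dependent).
#' @param seed RNG seed for the fan-in uniform initialisation.
#' @return parameter list of class \code{qa_params}, carrying the input
#'   dimensions so checkpoints can be validated at load time.
#' @export
init_params <- function(mcfg, d_atom_in = 11L, d_res_in = 20L, seed = 1L) {
  set.seed(seed)
  atom <- res <- list()
  if (mcfg$use_atom_stream) {
    d <- d_atom_in
    for (l in seq_len(mcfg$n_layers_atom)) {
      atom[[l]] <- .qa_init_conv_layer(d, mcfg$hidden_dim_atom, 2L)
      d <- mcfg$hidden_dim_atom
    }
  }
  if (mcfg$use_residue_stream) {
    d <- d_res_in
    for (l in seq_len(mcfg$n_layers_residue)) {
      res[[l]] <- .qa_init_conv_layer(d, mcfg$hidden_dim_residue, 1L)
      d <- mcfg$hidden_dim_residue
    }
  }
  d_cat <- (if (mcfg$use_atom_stream) mcfg$hidden_dim_atom else 0L) +
    (if (mcfg$use_residue_stream) mcfg$hidden_dim_residue else 0L)
  mlp <- list()
  d <- d_cat
  for (h in c(mcfg$mlp_hidden_dims, 1L)) {
    mlp[[length(mlp) + 1L]] <- list(W = .qa_init_mat(d, h),
                                    b = runif(h, -1 / sqrt(d), 1 / sqrt(d)))
    d <- h
  }
  structure(list(atom = atom, residue = res, mlp = mlp,
                 d_atom_in = as.integer(d_atom_in),
                 d_res_in = as.integer(d_res_in)),
            class = "qa_params")
}

#' One atom-level graph-convolution layer
#'
#' Each atom is updated from itself, the mean of its same-residue
#' neighbours and the mean of its cross-residue neighbours, through
#' separate weight matrices, followed by ReLU.  Atoms with an empty
#' neighbour set contribute a zero term for that aggregation.
#'
#' @param v n_atoms x d feature matrix.
#' @param g a \code{qa_atom_graph}.
#' @param p layer parameters: \code{W_c}, \code{W_s}, \code{W_o}
#'   (d x d_out) and bias \code{b}.
#' @return n_atoms x d_out matrix.
#' @export
atom_conv_layer <- function(v, g, p) {
  stopifnot(nrow(v) == g$n_atoms)
  Ss <- .qa_agg_matrix(g$same_residue_edges, g$n_same, g$n_atoms)
  So <- .qa_agg_matrix(g$cross_residue_edges, g$n_other, g$n_atoms)
  pre <- v %*% p$W_c + as.matrix(Ss %*% v) %*% p$W_s +
    as.matrix(So %*% v) %*% p$W_o
  pre <- sweep(pre, 2, p$b, "+")
  pmax(pre, 0)
}

#' One residue-level graph-convolution layer
#'
#' @param r n_residues x d feature matrix.
#' @param g a \code{qa_residue_graph}.
#' @param p layer parameters: \code{W_cr}, \code{W_r} (d x d_out) and
#'   bias \code{b}.
#' @return n_residues x d_out matrix.
#' @export
residue_conv_layer <- function(r, g, p) {
  stopifnot(nrow(r) == g$n_residues)
  S <- .qa_agg_matrix(g$edges, g$n_nbr, g$n_residues)
  pre <- r %*% p$W_cr + as.matrix(S %*% r) %*% p$W_r
  pre <- sweep(pre, 2, p$b, "+")
  pmax(pre, 0)
}

#' Per-residue max pooling of atom representations
#'
#' @param v n_atoms x d matrix of atom features.
#' @param s the \code{qa_structure} the atoms belong to.
#' @return n_residues x d matrix; row i is the elementwise maximum over
#'   the atoms of residue i.
#' @export
pool_atoms_to_residues <- function(v, s) {
  groups <- split(seq_len(nrow(v)), s$atoms$residue_index)
  if (any(lengths(groups) == 0L)) stop("residue with zero atoms")
  out <- matrix(NA_real_, length(groups), ncol(v))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    out[g, ] <- if (length(rows) == 1L) v[rows, ] else
      do.call(pmax, lapply(rows, function(r) v[r, ]))
  }
  out
}

# ---- fused forward/backward used for training ------------------------------

#' Precompute the per-decoy network inputs
#'
#' Bundles everything the forward pass needs: one-hot atom features,
#' residue embeddings, both graphs and their mean-aggregation operators,
#' and the residue membership of each atom.
#'
#' @param s a \code{qa_structure}.
#' @param provider residue [embedding_provider()].
#' @param gcfg a [graph_config()].
#' @return list of class \code{qa_decoy_input}.
#' @export
prepare_decoy <- function(s, provider = embedding_provider("onehot"),
                          gcfg = graph_config()) {
  ag <- build_atom_graph(s, gcfg)
  rg <- build_residue_graph(s, gcfg)
  af <- encode_atoms(s)
  rf <- embed_residues(qa_sequence(s), provider)
  groups <- split(seq_len(nrow(af)), s$atoms$residue_index)
  structure(list(
    atom_features = af, res_features = rf,
    S_same = .qa_agg_matrix(ag$same_residue_edges, ag$n_same, ag$n_atoms),
    S_other = .qa_agg_matrix(ag$cross_residue_edges, ag$n_other, ag$n_atoms),
    S_res = .qa_agg_matrix(rg$edges, rg$n_nbr, rg$n_residues),
    res_groups = groups, n_residues = s$length, n_atoms = nrow(af)),
    class = "qa_decoy_input")
}

# conv -> ReLU -> batch-norm (over the graph's nodes) -> dropout.
# Returns output, per-layer caches for backprop, and (in training)
# layers with updated running statistics.
.qa_stream_forward <- function(H, aggs, layers, mcfg, training) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    AH <- lapply(aggs, function(S) as.matrix(S %*% H))
    Wn <- intersect(c("W_s", "W_o"), names(p))
    pre <- H %*% p$W_c
    for (k in seq_along(AH)) pre <- pre + AH[[k]] %*% p[[Wn[k]]]
    pre <- sweep(pre, 2, p$b, "+")
    A <- pmax(pre, 0)
    n <- nrow(A)
    if (training && n > 1L) {
      mu <- colMeans(A)
      Ac <- sweep(A, 2, mu)
      v <- colMeans(Ac^2)
      layers[[l]]$bn_mean <- (1 - mcfg$bn_momentum) * p$bn_mean +
        mcfg$bn_momentum * mu
      layers[[l]]$bn_var <- (1 - mcfg$bn_momentum) * p$bn_var +
        mcfg$bn_momentum * v
    } else {
      mu <- p$bn_mean
      v <- p$bn_var
      Ac <- sweep(A, 2, mu)
    }
    isd <- 1 / sqrt(v + mcfg$bn_eps)
    Ahat <- sweep(Ac, 2, isd, "*")
    out <- sweep(sweep(Ahat, 2, p$bn_gamma, "*"), 2, p$bn_beta, "+")
    mask <- NULL
    if (training && mcfg$dropout > 0) {
      mask <- matrix((runif(length(out)) >= mcfg$dropout) /
                       (1 - mcfg$dropout), nrow(out), ncol(out))
      out <- out * mask
    }
    caches[[l]] <- list(H = H, AH = AH, pre = pre, Ahat = Ahat, isd = isd,
                        mask = mask, batch_bn = training && n > 1L)
    H <- out
  }
  list(out = H, caches = caches, layers = layers)
}

.qa_stream_backward <- function(G, caches, layers, aggs, mcfg) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    p <- layers[[l]]
    cc <- caches[[l]]
    if (!is.null(cc$mask)) G <- G * cc$mask
    # batch-norm backward
    dgamma <- colSums(G * cc$Ahat)
    dbeta <- colSums(G)
    dAhat <- sweep(G, 2, p$bn_gamma, "*")
    if (cc$batch_bn) {
      n <- nrow(G)
      s1 <- colSums(dAhat)
      s2 <- colSums(dAhat * cc$Ahat)
      dA <- sweep(dAhat, 2, s1 / n) - sweep(cc$Ahat, 2, s2 / n, "*")
      dA <- sweep(dA, 2, cc$isd, "*")
    } else {
      dA <- sweep(dAhat, 2, cc$isd, "*")
    }
    Gpre <- dA * (cc$pre > 0)
    g <- list(W_c = crossprod(cc$H, Gpre), b = colSums(Gpre),
              bn_gamma = dgamma, bn_beta = dbeta)
    Wn <- intersect(c("W_s", "W_o"), names(p))
    Gh <- Gpre %*% t(p$W_c)
    for (k in seq_along(cc$AH)) {
      g[[Wn[k]]] <- crossprod(cc$AH[[k]], Gpre)
      Gh <- Gh + as.matrix(Matrix::crossprod(aggs[[k]], Gpre %*% t(p[[Wn[k]]])))
    }
    grads[[l]] <- g
    G <- Gh
  }
  grads
}

#' Full forward pass of the quality network
#'
#' Runs both convolution streams, max-pools the atom stream per residue,
#' concatenates, applies the MLP and output activation, and averages the
#' per-residue scores into the global score.  In training mode batch
#' normalisation uses the statistics of the decoy's own nodes (and
#' updates the running statistics); in evaluation mode the stored
#' running statistics are used, so predictions are deterministic.
#'
#' @param params a \code{qa_params}.
#' @param input a \code{qa_decoy_input} from [prepare_decoy()].
#' @param mcfg the [model_config()] the parameters were built with.
#' @param training logical; enables batch statistics and dropout.
#' @return list with \code{per_residue}, \code{global_score}, updated
#'   \code{params} (running statistics; training mode only) and the
#'   \code{cache} consumed by [qa_backward()].
#' @export
qa_forward <- function(params, input, mcfg, training = FALSE) {
  a_fwd <- r_fwd <- NULL
  pooled <- NULL
  argmax <- NULL
  if (mcfg$use_atom_stream) {
    stopifnot(ncol(input$atom_features) == params$d_atom_in)
    a_fwd <- .qa_stream_forward(input$atom_features,
                                list(input$S_same, input$S_other),
                                params$atom, mcfg, training)
    params$atom <- a_fwd$layers
    V <- a_fwd$out
    groups <- input$res_groups
    pooled <- matrix(0, input$n_residues, ncol(V))
    argmax <- matrix(0L, input$n_residues, ncol(V))
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      if (length(rows) == 1L) {
        pooled[g, ] <- V[rows, ]
        argmax[g, ] <- rows
      } else {
        sub <- V[rows, , drop = FALSE]
        am <- max.col(t(sub), ties.method = "first")
        pooled[g, ] <- sub[cbind(am, seq_len(ncol(V)))]
        argmax[g, ] <- rows[am]
      }
    }
  }
  if (mcfg$use_residue_stream) {
    stopifnot(ncol(input$res_features) == params$d_res_in)
    r_fwd <- .qa_stream_forward(input$res_features, list(input$S_res),
                                params$residue, mcfg, training)
    params$residue <- r_fwd$layers
  }
  X <- cbind(pooled, if (!is.null(r_fwd)) r_fwd$out)

  mlp_cache <- vector("list", length(params$mlp))
  H <- X
  for (l in seq_along(params$mlp)) {
    p <- params$mlp[[l]]
    pre <- sweep(H %*% p$W, 2, p$b, "+")
    act <- if (l < length(params$mlp)) pmax(pre, 0) else pre
    mlp_cache[[l]] <- list(H = H, pre = pre)
    H <- act
  }
  z <- as.vector(H)
  per_res <- switch(mcfg$output_activation,
                    sigmoid = 1 / (1 + exp(-z)),
                    clamp = pmin(pmax(z, 0), 1),
                    none = z)
  if (anyNA(per_res) || any(!is.finite(per_res))) {
    stop("non-finite values in the forward pass")
  }
  list(per_residue = per_res, global_score = mean(per_res),
       params = params,
       cache = list(a_fwd = a_fwd, r_fwd = r_fwd, pooled_dim =
                      if (is.null(pooled)) 0L else ncol(pooled),
                    argmax = argmax, mlp = mlp_cache, z = z,
                    n_atoms = input$n_atoms))
}

# gradient of the scalar loss with respect to all parameters, given
# dLoss/dglobal_score
qa_backward <- function(params, input, mcfg, fwd, dglobal) {
  cc <- fwd$cache
  n_res <- input$n_residues
  dper <- rep(dglobal / n_res, n_res)
  z <- cc$z
  dz <- switch(mcfg$output_activation,
               sigmoid = dper * (1 / (1 + exp(-z))) * (1 - 1 / (1 + exp(-z))),
               clamp = dper * (z > 0 & z < 1),
               none = dper)
  G <- matrix(dz, n_res, 1L)
  mlp_grads <- vector("list", length(params$mlp))
  for (l in rev(seq_along(params$mlp))) {
    p <- params$mlp[[l]]
    mc <- cc$mlp[[l]]
    if (l < length(params$mlp)) G <- G * (mc$pre > 0)
    mlp_grads[[l]] <- list(W = crossprod(mc$H, G), b = colSums(G))
    G <- G %*% t(p$W)
  }
  # split concatenation
  atom_grads <- res_grads <- list()
  if (mcfg$use_atom_stream) {
    Gp <- G[, seq_len(cc$pooled_dim), drop = FALSE]
    GV <- matrix(0, cc$n_atoms, cc$pooled_dim)
    # atoms belong to exactly one residue, so (atom, column) pairs are
    # unique and the scatter needs no accumulation
    GV[cbind(as.vector(cc$argmax),
             rep(seq_len(cc$pooled_dim), each = n_res))] <- as.vector(Gp)
    atom_grads <- .qa_stream_backward(GV, cc$a_fwd$caches, params$atom,
                                      list(input$S_same, input$S_other), mcfg)
  }
  if (mcfg$use_residue_stream) {
    Gr <- G[, cc$pooled_dim + seq_len(ncol(G) - cc$pooled_dim), drop = FALSE]
    res_grads <- .qa_stream_backward(Gr, cc$r_fwd$caches, params$residue,
                                     list(input$S_res), mcfg)
  }
  list(atom = atom_grads, residue = res_grads, mlp = mlp_grads)
}

#' Predict decoy quality with a trained (or initialised) network
#'
#' @param params a \code{qa_params}.
#' @param input a \code{qa_decoy_input}, or a \code{qa_structure} (which
#'   is prepared with the supplied provider and graph config).
#' @param mcfg the matching [model_config()].
#' @param provider,gcfg used only when \code{input} is a structure.
#' @return list with \code{per_residue} scores and \code{global_score}
#'   (their mean), both in [0,1] under the sigmoid output.
#' @export
qa_predict <- function(params, input, mcfg,
                       provider = embedding_provider("onehot"),
                       gcfg = graph_config()) {
  if (inherits(input, "qa_structure")) {
    input <- prepare_decoy(input, provider, gcfg)
  }
  fwd <- qa_forward(params, input, mcfg, training = FALSE)
  list(per_residue = fwd$per_residue, global_score = fwd$global_score)
}
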