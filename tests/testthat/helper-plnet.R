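# Shared helpers: small configurations and fixtures used across tests.

small_cfg <- function(ocs = 0.25, n_steps = 2L, n_stages = 2L, n_classes = 1L,
                      input_size = 32L, base_channels = c(8L, 16L, 32L, 64L)) {
  plnet_config(ocs = ocs, n_steps = n_steps, n_stages = n_stages,
               base_channels = base_channels, n_classes = n_classes,
               input_size = input_size)
}

small_model <- function(seed = 42L, ...) {
  set.seed(seed)
  build_plnet(small_cfg(...))
}

rand_image <- function(n = 32L, ch = 3L, seed = 7L) {
  set.seed(seed)
  array(runif(n * n * ch), c(n, n, ch))
}

# numeric gradient of f at x by central differences
num_grad <- function(f, x, h = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-unrolled two-step forward pass: composes the merge primitives
# explicitly, without the recursion abstraction in plnet_graph(). Used as
# the independent oracle for ipl_forward() on fixed weights (depth-4
# configs with n_steps = 2).
unrolled_forward <- function(m, img) {
  ch <- m$config$channels
  L <- length(ch)
  stopifnot(L == 4L, m$config$n_steps == 2L)
  n <- dim(img)[1]
  cu <- function(name, x) plnet:::nd_val(plnet:::conv_unit_fwd(
    NULL, m, name, plnet:::tp_node(NULL, plnet:::to_internal(x)), FALSE))
  up <- function(d, x) plnet:::nd_val(plnet:::up_fwd(
    NULL, m, d, plnet:::tp_node(NULL, plnet:::to_internal(x))))
  hd <- function(s, x) plnet:::nd_val(plnet:::head_fwd(
    NULL, m, s, plnet:::tp_node(NULL, plnet:::to_internal(x))))
  drop4 <- function(a) { d <- dim(a); dim(a) <- c(d[1], d[2], d[4]); a }
  pool_cat <- function(a, b) {
    cat4 <- array(c(a, b), c(dim(a)[1:2], 1L, dim(a)[3] + dim(b)[3]))
    drop4(plnet:::nd_val(plnet:::op_maxpool2(NULL, plnet:::tp_node(NULL, cat4))))
  }
  zeros <- function(nn, c) array(0, c(nn, nn, c))
  one_pass <- function(s, B, last) {
    e <- list()
    e[[1]] <- drop4(cu(sprintf("enc1_s%d", s),
                       array(c(img, B[[1]] %||% zeros(n, ch[1])),
                             c(n, n, dim(img)[3] + ch[1]))))
    for (d in 2:(L - 1))
      e[[d]] <- drop4(cu(sprintf("enc%d_s%d", d, s),
                         pool_cat(e[[d - 1]],
                                  B[[d - 1]] %||% zeros(dim(e[[d - 1]])[1], ch[d - 1]))))
    if (last) {
      pooled <- drop4(plnet:::nd_val(plnet:::op_maxpool2(
        NULL, plnet:::tp_node(NULL, plnet:::to_internal(e[[L - 1]])))))
      bott <- drop4(cu("bott_refine", drop4(cu(sprintf("enc%d_s%d", L, s),
                                               drop4(cu("bott_entry", pooled))))))
      dtop <- L - 1L
    } else {
      bott <- drop4(cu("s1_refine", e[[L - 1]]))
      dtop <- L - 2L
    }
    below <- bott; dec <- list()
    for (d in seq.int(dtop, 1)) {
      merged <- fsc_merge(m, e[[d]], drop4(up(d, below)), level = d, step = s)
      dec[[d]] <- drop4(cu(sprintf("decr%d", d), merged))
      below <- dec[[d]]
    }
    dec
  }
  B <- list(NULL, NULL, NULL)
  for (s in 1:2) B <- one_pass(s, B, last = FALSE)
  y1 <- drop4(hd(1, B[[1]]))
  for (s in 1:2) B <- one_pass(s, B, last = TRUE)
  y2 <- drop4(hd(2, B[[1]]))
  list(y1 = y1, y2 = y2)
}
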