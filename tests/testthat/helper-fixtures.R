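# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# A small random volume with a non-trivial (cropped) frame.
fixture_volume <- function(shape = c(12L, 10L, 8L), seed = 1L) {
  withr::with_seed(seed, {
    parent <- c(40L, 40L, 40L)
    st <- vapply(parent - shape, function(m) sample.int(m, 1L) - 1L, integer(1))
    f <- crop_frame(whole_body_frame(), parent, cbind(st, st + shape))
    volume(array(runif(prod(shape)), shape), spacing = c(2, 2, 3), frame = f)
  })
}

# Tiny trained codec + phantom corpus (16^3, desk architecture scaled down),
# cached per session because several tests reuse it.
.fx_env <- new.env(parent = emptyenv())

fixture_codec <- function() {
  if (!is.null(.fx_env$codec)) return(.fx_env$codec)
  corp <- lapply(1:4, function(i)
    generate_phantom(phantom_spec(shape = c(16L, 16L, 16L),
                                  seed = derive_seed(71L, paste0("c", i)))))
  codec <- codec_init(codec_config(K = 16L, n_z = 8L, width = 12L), seed = 3L)
  codec <- train_codec(codec, lapply(corp, `[[`, "primary"), steps = 60L,
                       crop_sizes = c(8L, 12L), seed = 4L)
  .fx_env$codec <- list(codec = codec, corpus = corp)
  .fx_env$codec
}

# A tiny sequence model memorizing one fixed sequence (near-one-hot
# distributions), reused by seqmodel and anomaly tests.
fixture_memorized <- function() {
  if (!is.null(.fx_env$memo)) return(.fx_env$memo)
  cfg <- seq_config(K = 6L, K_aux = 5L, B = 3L, n_layers = 2L, n_heads = 2L,
                    d = 8L, max_len = 12L)
  s <- c(0L, 3L, 5L, 2L, 1L, 4L, 0L, 2L)
  cond <- conditioning(aux = c(1L, 0L, 4L, 2L, 3L, 1L, 0L, 2L),
                       sp = c(0L, 5L, 9L, 26L, 3L, 7L, 11L, 2L))
  model <- train_seqmodel(seq_init(cfg, seed = 8L),
                          list(list(s = s, cond = cond)),
                          steps = 400L, lr = 1e-2, seed = 9L)
  .fx_env$memo <- list(model = model, s = s, cond = cond, cfg = cfg)
  .fx_env$memo
}
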