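test_that("network configs and presets follow the two-stage design", {
  expect_error(net_config("WCE", base_filters = 0), "positive")
  expect_error(net_config("WCE", in_channels = 2), "odd")
  s1 <- ensemble_config("stage1", base_filters = c(32L, 64L))
  expect_length(s1, 3L)
  expect_equal(vapply(s1, `[[`, character(1), "loss"),
               c("WCE", "LV", "LV"))
  expect_equal(vapply(s1, `[[`, integer(1), "base_filters"),
               c(32L, 32L, 64L))
  s2 <- ensemble_config("stage2", base_filters = c(4L, 8L))
  expect_length(s2, 6L)
  expect_setequal(
    vapply(s2, function(cf) paste(cf$loss, cf$base_filters), character(1)),
    c("WCE 4", "WCE 8", "DC 4", "DC 8", "LV 4", "LV 8"))
})

test_that("forward pass maps the study input shape to five class channels", {
  net <- build_net(net_config("WCE", base_filters = 4L, seed = 1))
  sm <- list(image = matrix(0, 288, 384), lung = matrix(1L, 288, 384))
  sc <- predict_scores(net, sm)
  expect_equal(dim(sc), c(288L, 384L, 5L))
  expect_true(all(is.finite(sc)))  # all-air input stays finite
  # inputs that cannot survive four halvings are rejected
  expect_error(predict_scores(net, list(image = matrix(0, 40, 48))),
               "divisible by 16")
})

test_that("parameter count scales ~4x with doubled base filters", {
  layout_count <- function(f) {
    # independent arithmetic over the layer list
    ch <- f * c(1, 2, 4, 8, 16)
    convs <- list(c(1, ch[1]), c(ch[1], ch[1]))
    for (l in 2:5) convs <- c(convs, list(c(ch[l - 1], ch[l]),
                                          c(ch[l], ch[l])))
    for (l in 4:1) convs <- c(convs, list(c(ch[l + 1], ch[l]),
                                          c(2 * ch[l], ch[l]),
                                          c(ch[l], ch[l])))
    n <- sum(vapply(convs, function(cc) 9 * cc[1] * cc[2] + 3 * cc[2],
                    numeric(1)))
    n + ch[1] * 5 + 5
  }
  n4 <- parameter_count(build_net(net_config("DC", base_filters = 4L)))
  n8 <- parameter_count(build_net(net_config("DC", base_filters = 8L)))
  expect_equal(n4, layout_count(4))
  expect_equal(n8, layout_count(8))
  expect_gt(n8 / n4, 3.5)
  expect_lt(n8 / n4, 4.2)
})

test_that("initialisation and training are deterministic under a seed", {
  cfg <- net_config("DC", base_filters = 2L, seed = 5)
  expect_identical(build_net(cfg)$params, build_net(cfg)$params)
  sm <- demo_sample()
  a <- train_net(build_net(cfg), list(sm), epochs = 2, seed = 3)
  b <- train_net(build_net(cfg), list(sm), epochs = 2, seed = 3)
  expect_identical(a$params, b$params)
})

test_that("training reduces the loss on a small phantom sample set", {
  cs <- generate_case(phantom_spec(n_patients = 1, seed = 5), 1, 4)
  plan <- slice_plan(cs, target = c(32L, 48L))
  samples <- make_samples(cs, plan,
                          slices = plan$retained[seq(1, 20, length.out =
                                                       min(20,
                                                           length(plan$retained)))])
  for (kind in c("WCE", "DC", "LV")) {
    net <- build_net(net_config(kind, base_filters = 4L, seed = 2))
    tr <- train_net(net, samples, epochs = 3, lr = 1e-2, seed = 1)
    h <- attr(tr, "history")
    expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  }
})

test_that("validation-based early stopping halts and keeps the best model", {
  sm <- demo_sample()
  net <- build_net(net_config("WCE", base_filters = 2L, seed = 6))
  tr <- train_net(net, list(sm), epochs = 30L, lr = 1e-3,
                  val_samples = list(sm), patience = 1L, seed = 2)
  h <- attr(tr, "history")
  expect_true(all(is.finite(h$val_loss)))
  # either it ran out of epochs improving every time, or it stopped early
  expect_lte(nrow(h), 30L)
  if (nrow(h) < 30L) expect_gte(nrow(h), 2L)
})

test_that("a tiny net overfits one sample under the Lovasz loss", {
  sm <- demo_sample()
  net <- build_net(net_config("LV", base_filters = 8L, seed = 1))
  tr <- train_net(net, list(sm), epochs = 200, lr = 1e-2, seed = 1)
  expect_lt(min(attr(tr, "history")$train_loss), 0.05)
})

test_that("network scores commute with softmax for label decisions", {
  net <- build_net(net_config("LV", base_filters = 2L, seed = 8))
  sm <- demo_sample()
  sc <- predict_scores(net, sm)
  d <- dim(sc)
  flat <- matrix(sc, d[1] * d[2], d[3])
  p <- rildseg:::softmax_rows(flat)
  expect_equal(max.col(flat, ties.method = "first"),
               max.col(p, ties.method = "first"))
  # argmax invariant under a per-voxel constant shift of all channels
  expect_equal(max.col(flat + 7, ties.method = "first"),
               max.col(flat, ties.method = "first"))
})

test_that("logit-sum fusion follows the summed confidence", {
  # two members, two voxels: member 1 prefers class 2 by +2 on voxel 1;
  # member 2 prefers class 3 by -1 relative margins; sums decide
  s1 <- array(0, dim = c(1, 2, 5)); s2 <- array(0, dim = c(1, 2, 5))
  s1[1, 1, 2] <- 2; s2[1, 1, 3] <- 1    # voxel 1: class 2 wins (2 > 1)
  s1[1, 2, 4] <- 1; s2[1, 2, 5] <- 3    # voxel 2: class 5 wins (3 > 1)
  lung <- matrix(1L, 1, 2)
  expect_equal(as.vector(rildseg:::fuse_scores(list(s1, s2), lung)),
               c(2L, 5L))
  # opposing preferences on the same class pair
  a <- array(0, dim = c(1, 1, 5)); b <- array(0, dim = c(1, 1, 5))
  a[1, 1, 1] <- 2; b[1, 1, 2] <- 1   # +2 for class 1 vs +1 for class 2
  expect_equal(as.vector(rildseg:::fuse_scores(list(a, b),
                                               matrix(1L, 1, 1))), 1L)
  # outside-lung voxels carry the sentinel
  expect_equal(as.vector(rildseg:::fuse_scores(list(s1, s2),
                                               matrix(0L, 1, 2))),
               rep(OUTSIDE, 2))
})

test_that("ensembles of identical members equal the single member", {
  net <- build_net(net_config("DC", base_filters = 2L, seed = 4))
  sm <- demo_sample()
  single <- ensemble_predict(list(net), sm)
  triple <- ensemble_predict(list(net, net, net), sm)
  expect_identical(triple, single)
  # member order cannot matter
  net2 <- build_net(net_config("LV", base_filters = 2L, seed = 9))
  net3 <- build_net(net_config("WCE", base_filters = 4L, seed = 2))
  ab <- ensemble_predict(list(net, net2, net3), sm)
  ba <- ensemble_predict(list(net3, net, net2), sm)
  expect_identical(ab, ba)
  expect_error(ensemble_predict(list(), sm), "empty")
})

test_that("whole-case prediction labels every lung voxel and only those", {
  cs <- generate_case(tiny_spec(seed = 10L), 1, 2)
  plan <- slice_plan(cs, target = c(32L, 48L))
  nets <- list(build_net(net_config("WCE", base_filters = 2L, seed = 3)))
  pred <- predict_case(nets, cs, plan)
  expect_s3_class(pred, "label_map")   # vocabulary validated on build
  inside <- cs$mask$voxels == 1L
  expect_true(all(pred$voxels[inside] %in% 1:5))
  expect_true(all(pred$voxels[!inside] == OUTSIDE))
})

test_that("network backprop agrees with finite differences", {
  set.seed(42)
  net <- build_net(net_config("WCE", base_filters = 2L, seed = 7))
  H <- 32L; W <- 32L
  img <- array(stats::runif(H * W), dim = c(H, W, 1))
  lab <- matrix(sample(1:5, H * W, TRUE), H, W)
  w <- c(1, 2, 0.5, 1.5, 1)
  grad_fn <- function(logits) {
    d <- dim(logits)
    lg <- rildseg:::loss_grad_logits("WCE", matrix(logits, d[1] * d[2],
                                                   d[3]),
                                     as.vector(lab), w)
    list(loss = lg$loss, grad = array(lg$grad, dim = d))
  }
  st <- rildseg:::cpp_unet_step(net$params, img, grad_fn)
  loss_at <- function(params) {
    lo <- rildseg:::cpp_unet_logits(params, img)
    d <- dim(lo)
    rildseg:::loss_grad_logits("WCE", matrix(lo, d[1] * d[2], d[3]),
                               as.vector(lab), w)$loss
  }
  h <- 1e-5
  for (ui in c(1L, 6L, 12L, 18L, 23L)) {
    for (fld in c("W", if (ui != 23L) "g")) {
      v <- net$params[[ui]][[fld]]
      for (j in sample(length(v), min(3, length(v)))) {
        p1 <- net$params; p1[[ui]][[fld]][j] <- p1[[ui]][[fld]][j] + h
        p2 <- net$params; p2[[ui]][[fld]][j] <- p2[[ui]][[fld]][j] - h
        fd <- (loss_at(p1) - loss_at(p2)) / (2 * h)
        an <- st$grads[[ui]][[fld]][j]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-3)
      }
    }
  }
})
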