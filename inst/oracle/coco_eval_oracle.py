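#!/usr/bin/env python
"""Independent COCO-style detection/segmentation evaluator.

Follows the published COCO evaluation algorithm (greedy best-IoU matching
per threshold, 101-point interpolated precision, per-image detection caps)
for a single category with no crowd regions. Used as a cross-check oracle
for the R implementation; shares no code with it.

Usage: coco_eval_oracle.py GT.json RESULTS.json {bbox|segm}
Prints a JSON object with AP, AP50, AP75, AR1, AR10, AR100 (fractions).
"""
import json
import sys

import numpy as np

IOU_THRS = np.round(np.arange(0.5, 0.951, 0.05), 10)
REC_THRS = np.round(np.arange(0.0, 1.001, 0.01), 10)
MAX_DETS = (1, 10, 100)


def decode_rle(seg):
    h, w = seg["size"]
    counts = np.asarray(seg["counts"], dtype=np.int64)
    vals = np.zeros(counts.sum(), dtype=bool)
    pos = 0
    flag = False
    for c in counts:
        if flag:
            vals[pos:pos + c] = True
        pos += c
        flag = not flag
    return vals.reshape((w, h)).T  # column-major


def fill_polygon(xy, h, w):
    """Even-odd fill sampled at pixel centers (c+0.5, r+0.5)."""
    pts = np.asarray(xy, dtype=float).reshape(-1, 2)
    mask = np.zeros((h, w), dtype=bool)
    x, y = pts[:, 0], pts[:, 1]
    x2, y2 = np.roll(x, -1), np.roll(y, -1)
    for r in range(h):
        yc = r + 0.5
        crosses = (y <= yc) != (y2 <= yc)
        if not crosses.any():
            continue
        xi = x[crosses] + (yc - y[crosses]) * (x2[crosses] - x[crosses]) / (
            y2[crosses] - y[crosses])
        xi.sort()
        for k in range(0, len(xi) - 1, 2):
            c0 = max(int(np.ceil(xi[k] - 0.5)), 0)
            c1 = min(int(np.ceil(xi[k + 1] - 0.5)) - 1, w - 1)
            if c1 >= c0:
                mask[r, c0:c1 + 1] = True
    return mask


def decode_segmentation(seg, h, w):
    if isinstance(seg, dict) and "counts" in seg:
        return decode_rle(seg)
    mask = np.zeros((h, w), dtype=bool)
    for poly in seg:
        mask |= fill_polygon(poly, h, w)
    return mask


def box_iou(d, g):
    d = np.asarray(d, dtype=float).reshape(-1, 4)
    g = np.asarray(g, dtype=float).reshape(-1, 4)
    ix = np.maximum(
        np.minimum(d[:, None, 0] + d[:, None, 2], g[None, :, 0] + g[None, :, 2])
        - np.maximum(d[:, None, 0], g[None, :, 0]), 0)
    iy = np.maximum(
        np.minimum(d[:, None, 1] + d[:, None, 3], g[None, :, 1] + g[None, :, 3])
        - np.maximum(d[:, None, 1], g[None, :, 1]), 0)
    inter = ix * iy
    union = (d[:, 2] * d[:, 3])[:, None] + (g[:, 2] * g[:, 3])[None, :] - inter
    out = np.where(union > 0, inter / np.maximum(union, 1e-12), 0.0)
    return out


def mask_iou(dmasks, gmasks):
    out = np.zeros((len(dmasks), len(gmasks)))
    for i, dm in enumerate(dmasks):
        for j, gm in enumerate(gmasks):
            u = np.logical_or(dm, gm).sum()
            out[i, j] = np.logical_and(dm, gm).sum() / u if u else 0.0
    return out


def main():
    gt_path, dt_path, task = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(gt_path) as fh:
        gt = json.load(fh)
    with open(dt_path) as fh:
        dt = json.load(fh)

    imgs = sorted(gt["images"], key=lambda im: im["id"])
    ids = [im["id"] for im in imgs]
    hw = {im["id"]: (im["height"], im["width"]) for im in imgs}
    g_by_img = {i: [] for i in ids}
    for a in gt["annotations"]:
        g_by_img[a["image_id"]].append(a)
    d_by_img = {i: [] for i in ids}
    for d in dt:
        d_by_img[d["image_id"]].append(d)

    T = len(IOU_THRS)
    per_img = []
    n_gt = 0
    for i in ids:
        gs, ds = g_by_img[i], d_by_img[i]
        scores = np.array([d["score"] for d in ds], dtype=float)
        order = np.argsort(-scores, kind="mergesort")[:max(MAX_DETS)]
        n_gt += len(gs)
        if len(order) and len(gs):
            if task == "segm":
                h, w = hw[i]
                dm = [decode_segmentation(ds[k]["segmentation"], h, w)
                      for k in order]
                gm = [decode_segmentation(g["segmentation"], h, w) for g in gs]
                ious = mask_iou(dm, gm)
            else:
                ious = box_iou([ds[k]["bbox"] for k in order],
                               [g["bbox"] for g in gs])
        else:
            ious = np.zeros((len(order), len(gs)))
        dtm = np.zeros((T, len(order)), dtype=int)
        for t, thr in enumerate(IOU_THRS):
            used = np.zeros(len(gs), dtype=bool)
            lim = min(thr, 1 - 1e-10)
            for di in range(len(order)):
                best = lim - 1e-10
                match = -1
                for gi in range(len(gs)):
                    if used[gi] or ious[di, gi] < best:
                        continue
                    best = ious[di, gi]
                    match = gi
                if match >= 0:
                    used[match] = True
                    dtm[t, di] = match + 1
        per_img.append((scores[order], dtm))

    if n_gt == 0:
        report = {k: -1.0 for k in ("AP", "AP50", "AP75", "AR1", "AR10", "AR100")}
        print(json.dumps(report))
        return

    def accumulate(k):
        scores = np.concatenate([p[0][:k] for p in per_img]) if per_img else \
            np.zeros(0)
        aps = np.zeros(T)
        recalls = np.zeros(T)
        for t in range(T):
            matched = np.concatenate([p[1][t, :k] for p in per_img]) > 0
            if scores.size == 0:
                continue
            order = np.argsort(-scores, kind="mergesort")
            tps = np.cumsum(matched[order])
            fps = np.cumsum(~matched[order])
            rc = tps / n_gt
            pr = tps / np.maximum(tps + fps, 1e-12)
            recalls[t] = rc[-1]
            for i in range(len(pr) - 1, 0, -1):
                if pr[i] > pr[i - 1]:
                    pr[i - 1] = pr[i]
            inds = np.searchsorted(rc, REC_THRS, side="left")
            q = np.zeros(len(REC_THRS))
            ok = inds < len(pr)
            q[ok] = pr[inds[ok]]
            aps[t] = q.mean()
        return aps, recalls

    aps100, rec100 = accumulate(100)
    _, rec10 = accumulate(10)
    _, rec1 = accumulate(1)
    report = {
        "AP": float(aps100.mean()),
        "AP50": float(aps100[0]),
        "AP75": float(aps100[5]),
        "AR1": float(rec1.mean()),
        "AR10": float(rec10.mean()),
        "AR100": float(rec100.mean()),
    }
    print(json.dumps(report))


if __name__ == "__main__":
    main()
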