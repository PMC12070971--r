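model	ap50_95	ap50	ap75
YOLOv5s	71.43	93.06	83.12
YOLOv8s	72.47	93.17	83.77
YOLOv9s	72.92	93.28	82.66
YOLOv10s	73.52	93.53	83.97
Mamba-YOLO-T	70.29	92.70	81.15
YOLOv11s	72.54	93.26	82.57
YOLO-SDD-s	75.60	94.04	85.38
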