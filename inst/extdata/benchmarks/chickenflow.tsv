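model	ap50_95	ap50	ap75	flops_g	params_m
YOLOv5n	75.27	95.86	88.09	4.1	1.9
YOLOv5s	78.64	96.12	90.48	16.5	7.2
YOLOv5m	81.41	96.38	91.29	49.0	21.2
YOLOv7-tiny	74.17	95.54	86.77	13.7	6.2
YOLOv7	79.07	96.48	89.33	104.7	36.9
YOLOv8n	79.01	96.28	90.90	8.7	3.2
YOLOv8s	82.14	96.85	92.02	28.6	11.2
YOLOv8m	84.03	96.44	91.95	78.9	25.9
YOLOv9t	77.58	96.20	89.25	7.7	2.0
YOLOv9s	81.04	96.65	91.55	26.7	7.2
YOLOv9m	83.51	96.76	92.61	76.8	20.1
YOLOv10n	79.97	96.66	91.51	8.4	2.7
YOLOv10s	82.64	96.45	92.57	24.8	8.6
YOLOv10m	84.55	96.84	92.73	64.0	16.5
Mamba-YOLO-T	79.33	96.07	90.59	14.3	6.1
Mamba-YOLO-B	82.43	96.76	92.02	49.7	21.8
YOLOv11n	79.50	96.81	90.96	6.5	2.6
YOLOv11s	82.40	97.01	92.00	21.5	9.4
YOLOv11m	84.01	96.86	92.55	68.0	20.1
YOLO-SDD-n	81.19	96.90	92.01	11.4	2.6
YOLO-SDD-s	84.27	97.17	93.24	28.8	9.0
YOLO-SDD-m	85.65	97.30	93.06	77.1	22.0
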