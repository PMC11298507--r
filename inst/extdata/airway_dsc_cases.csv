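case,model,baseline,ensemble
1,nnunet_in_lrelu,87.06,86.85
2,nnunet_in_lrelu,82.33,83.14
3,nnunet_in_lrelu,77.96,81.23
4,nnunet_in_lrelu,86.50,88.29
5,nnunet_in_lrelu,88.07,88.17
6,nnunet_in_lrelu,96.58,98.06
7,nnunet_in_lrelu,92.38,94.09
8,nnunet_in_lrelu,97.00,97.35
9,nnunet_in_lrelu,83.47,97.58
10,nnunet_in_lrelu,85.22,90.74
1,nnunet_bn_relu,86.65,86.86
2,nnunet_bn_relu,81.89,83.29
3,nnunet_bn_relu,78.01,81.58
4,nnunet_bn_relu,87.24,88.60
5,nnunet_bn_relu,87.23,87.50
6,nnunet_bn_relu,93.70,95.48
7,nnunet_bn_relu,86.39,92.40
8,nnunet_bn_relu,88.31,97.19
9,nnunet_bn_relu,82.04,91.32
10,nnunet_bn_relu,85.12,90.93
1,dilated_unet,85.27,86.10
2,dilated_unet,81.56,81.81
3,dilated_unet,78.99,81.40
4,dilated_unet,83.20,86.75
5,dilated_unet,79.71,85.21
6,dilated_unet,88.69,93.28
7,dilated_unet,78.56,79.80
8,dilated_unet,91.13,94.55
9,dilated_unet,72.59,76.80
10,dilated_unet,79.57,92.27
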