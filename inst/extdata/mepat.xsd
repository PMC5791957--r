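<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the package's MEPAT dialect: the portable calibration
     artefact <TF, ES, CH, CLS, OP, PER> with UID and timestamps. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:simpleType name="numText">
    <xs:restriction base="xs:string">
      <xs:pattern value="\s*[-+0-9.eE]+(\s+[-+0-9.eE]+)*\s*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="uuid">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="itemList">
    <xs:sequence>
      <xs:element name="item" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
          <xs:attribute name="value" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:element name="mepat">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="TF" type="itemList"/>
        <xs:element name="ES">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="cycles" type="numText"/>
              <xs:element name="dpi" type="xs:double"/>
              <xs:element name="thickness_mm" type="xs:double"/>
              <xs:element name="segmentation">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="spatial_bandwidth" type="xs:double"/>
                    <xs:element name="range_bandwidth" type="xs:double"/>
                    <xs:element name="dist_weight" type="xs:double"/>
                    <xs:element name="restarts" type="xs:double"/>
                    <xs:element name="seed" type="xs:double"/>
                    <xs:element name="variant" type="xs:string"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="CH">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="feature" minOccurs="1" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="code" type="xs:string" use="required"/>
                  <xs:attribute name="q" type="xs:double" use="required"/>
                  <xs:attribute name="center" type="xs:double" use="required"/>
                  <xs:attribute name="scale" type="xs:double" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="CLS">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="stage" minOccurs="1" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="W1" type="numText"/>
                    <xs:element name="W2" type="numText"/>
                  </xs:sequence>
                  <xs:attribute name="target_t" type="xs:integer" use="required"/>
                  <xs:attribute name="h" type="xs:integer" use="required"/>
                  <xs:attribute name="k" type="xs:integer" use="required"/>
                  <xs:attribute name="threshold" type="xs:double" use="required"/>
                  <xs:attribute name="mcc_sg" type="xs:double" use="required"/>
                  <xs:attribute name="seed" type="xs:integer" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="OP" type="itemList"/>
        <xs:element name="PER">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="global">
                <xs:complexType>
                  <xs:attribute name="mcc" type="xs:double" use="required"/>
                  <xs:attribute name="sensitivity" type="xs:double" use="required"/>
                  <xs:attribute name="specificity" type="xs:double" use="required"/>
                  <xs:attribute name="accuracy" type="xs:double" use="required"/>
                  <xs:attribute name="n_unclassified" type="xs:integer" use="required"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="stage" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="target_t" type="xs:integer" use="required"/>
                  <xs:attribute name="mcc" type="xs:double" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="uid" type="uuid" use="required"/>
      <xs:attribute name="created" type="xs:string" use="required"/>
      <xs:attribute name="uploaded" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
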